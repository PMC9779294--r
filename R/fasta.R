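#' Read protein or DNA sequences from FASTA
#'
#' Thin wrappers over Biostrings' FASTA readers with the package's record
#' conventions: record ids are taken from the header up to the first
#' whitespace, sequences are upper-cased, duplicate ids and empty records
#' are errors. CRLF and LF files parse identically.
#'
#' @param path FASTA file.
#' @return named character vector of sequences (names are record ids).
#' @export
read_protein_fasta <- function(path) {
  .read_fasta(path, Biostrings::readBStringSet, .aa_alphabet)
}

#' @rdname read_protein_fasta
#' @export
read_dna_fasta <- function(path) {
  .read_fasta(path, Biostrings::readBStringSet, c("A", "C", "G", "T", "N"))
}

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

.read_fasta <- function(path, reader, alphabet) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- reader(path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(seqs)))
    stop("empty FASTA record: ", ids[which(!nzchar(seqs))[1L]])
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[anyDuplicated(ids)])
  bad <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1L]]),
                 c(alphabet, "*"))
  if (length(bad))
    stop("unexpected sequence symbol(s): ", paste(bad, collapse = ", "))
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
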