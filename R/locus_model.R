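#' Construct a gene model
#'
#' A gene model holds the exon layout, strand and per-assembly transcription
#' start site (TSS) anchors for one locus. Genomic coordinates are 1-based
#' inclusive throughout the package (browser display convention); BED and
#' bedGraph readers/writers convert to and from 0-based half-open at the
#' file boundary.
#'
#' Exons are given in transcription order (exon 1 first). On the minus
#' strand exon 1 therefore carries the greatest genomic coordinates, and the
#' TSS is the maximum coordinate of exon 1; on the plus strand it is the
#' minimum.
#'
#' @param name gene identifier.
#' @param chromosome chromosome identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (start, end) of 1-based inclusive genomic
#'   exon coordinates, rows in transcription order.
#' @param tss_by_assembly named numeric vector mapping assembly name to the
#'   TSS coordinate in that assembly. At least one anchor is required; the
#'   first is taken to be the assembly of `exons`.
#' @param cds optional two-column matrix of per-exon CDS sub-intervals in
#'   the same coordinates (rows parallel to `exons`; `NA` rows for
#'   non-coding exons). Used by the synthetic generator for translation.
#' @return an object of class `gene_model`.
#' @examples
#' gm <- gene_model("G", "chrS", "-",
#'                  exons = cbind(c(900, 500, 200), c(1000, 600, 300)),
#'                  tss_by_assembly = c(sim1 = 1000))
#' gene_length(gm)
#' @export
gene_model <- function(name, chromosome, strand, exons, tss_by_assembly,
                       cds = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- as.matrix(exons)
  if (ncol(exons) != 2L) stop("exons must have two columns (start, end)")
  storage.mode(exons) <- "double"
  if (any(exons[, 1L] > exons[, 2L])) stop("exon start > end")
  ## transcription order: '+' ascending, '-' descending
  ord <- if (strand == "+") order(exons[, 1L]) else order(-exons[, 1L])
  if (!identical(ord, seq_len(nrow(exons))))
    stop("exons must be supplied in transcription order")
  if (nrow(exons) > 1L) {
    g <- exons[order(exons[, 1L]), , drop = FALSE]
    if (any(g[-1L, 1L] <= g[-nrow(g), 2L])) stop("exons overlap")
  }
  if (is.null(names(tss_by_assembly)) || any(!nzchar(names(tss_by_assembly))))
    stop("tss_by_assembly must be a named vector")
  tss_native <- tss_by_assembly[[1L]]
  tss_exon1 <- if (strand == "-") max(exons[1L, ]) else min(exons[1L, ])
  if (tss_native != tss_exon1)
    stop("TSS anchor does not equal the transcription-direction first ",
         "nucleotide of exon 1 (expected ", tss_exon1, ")")
  structure(list(name = name, chromosome = chromosome, strand = strand,
                 exons = exons, tss_by_assembly = tss_by_assembly, cds = cds),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model:", x$name, " ", x$chromosome, "(", x$strand, "), ",
      nrow(x$exons), " exons, span ", format(gene_span(x)[1L], big.mark = ","),
      "-", format(gene_span(x)[2L], big.mark = ","), "\n", sep = "")
  cat("  TSS anchors:",
      paste(names(x$tss_by_assembly), format(x$tss_by_assembly, big.mark = ","),
            sep = " = ", collapse = "; "), "\n")
  invisible(x)
}

#' Genomic span and length of a gene model
#'
#' @param gene a [gene_model].
#' @return `gene_span()`: c(start, end) 1-based inclusive; `gene_length()`:
#'   length in bases.
#' @export
gene_span <- function(gene) {
  c(min(gene$exons), max(gene$exons))
}

#' @rdname gene_span
#' @export
gene_length <- function(gene) {
  sp <- gene_span(gene)
  sp[2L] - sp[1L] + 1
}

#' The human MECP2 gene model
#'
#' Minus-strand, four-exon gene on chrX with the TSS (transcription-direction
#' first nucleotide of exon 1, including the 5' UTR) anchored at
#' chrX:153,363,188 (hg19) and chrX:154,097,717 (hg38). The internal exon
#' boundaries shipped here are approximate (only the TSS anchors and the
#' gene span enter any computation); the span end is the annotated 3' end of
#' the long-3'UTR transcript.
#'
#' @return a [gene_model].
#' @export
mecp2_gene_model <- function() {
  ## hg19 coordinates; exon boundaries approximate except the TSS
  gene_model(
    name = "MECP2", chromosome = "chrX", strand = "-",
    exons = cbind(start = c(153363038, 153361096, 153360090, 153287263),
                  end   = c(153363188, 153361261, 153360212, 153296204)),
    tss_by_assembly = c(hg19 = 153363188, hg38 = 154097717)
  )
}

## ------------------------------------------------------------------------
## transcript record tables (mirrors of the published database summaries)

.tx_required_cols <- c("accession", "source_db", "product_isoform",
                       "review_status", "evidence", "biotype", "tsl",
                       "cds_incomplete")
.tx_biotypes <- c("protein coding", "nonsense mediated decay", "other")
.tx_cds <- c("none", "5prime", "3prime", "both")

#' Parse a transcript record table
#'
#' Reads a tab-separated mirror of a database transcript summary (one row
#' per transcript). Lines starting with `#` are treated as provenance
#' comments. A `-` cell is parsed as missing (`NA`).
#'
#' Required columns: `accession`, `source_db`, `product_isoform`,
#' `review_status` (`reviewed`/`unreviewed`), `evidence`, `biotype`
#' (`protein coding`, `nonsense mediated decay`, `other`), `tsl`
#' (integer 1-5 or `-`), `cds_incomplete` (`none`, `5prime`, `3prime`,
#' `both`).
#'
#' @param path path to the TSV file.
#' @return a data.frame of class `transcript_records`, one row per record.
#' @seealso [summarize_products()]
#' @export
parse_transcript_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL)
  missing_cols <- setdiff(.tx_required_cols, names(df))
  if (length(missing_cols))
    stop("transcript table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[, .tx_required_cols]
  df[df == "-"] <- NA
  if (nrow(df)) {
    check_enum <- function(col, allowed) {
      vals <- df[[col]]
      bad <- which(!is.na(vals) & !vals %in% allowed)
      if (length(bad))
        stop("row ", bad[1L], ": invalid ", col, " '", vals[bad[1L]], "'")
    }
    check_enum("review_status", c("reviewed", "unreviewed"))
    check_enum("biotype", .tx_biotypes)
    check_enum("cds_incomplete", .tx_cds)
    tsl <- suppressWarnings(as.integer(df$tsl))
    bad <- which(!is.na(df$tsl) & (is.na(tsl) | tsl < 1L | tsl > 5L))
    if (length(bad))
      stop("row ", bad[1L], ": tsl must be an integer in 1..5, got '",
           df$tsl[bad[1L]], "'")
    df$tsl <- tsl
    df$cds_incomplete[is.na(df$cds_incomplete)] <- "none"
    bad <- which(df$review_status == "reviewed" &
                   (is.na(df$evidence) | !nzchar(df$evidence)))
    if (length(bad))
      stop("row ", bad[1L], ": reviewed record lacks evidence text")
  } else {
    df$tsl <- integer(0)
  }
  class(df) <- c("transcript_records", "data.frame")
  df
}

#' Summarize protein products of a transcript record set
#'
#' Counts how many transcript records map to each annotated protein
#' isoform product. Records without a product are excluded from the counts
#' and reported in the `"no_product"` attribute.
#'
#' @param records a `transcript_records` data.frame (one source database).
#' @return named integer vector of record counts per product isoform, with
#'   attribute `no_product` listing accessions lacking a product.
#' @export
summarize_products <- function(records) {
  if (length(unique(stats::na.omit(records$source_db))) > 1L)
    stop("records must come from a single source database")
  has <- !is.na(records$product_isoform)
  counts <- table(records$product_isoform[has])
  out <- stats::setNames(as.integer(counts), names(counts))
  attr(out, "no_product") <- records$accession[!has]
  out
}

#' Write a transcript record table
#'
#' Inverse of [parse_transcript_table()]: missing values serialize as
#' `-`, so a parse/write round trip reproduces the mirror file
#' field-for-field.
#'
#' @param records a `transcript_records` data.frame.
#' @param path output TSV file.
#' @export
write_transcript_table <- function(records, path) {
  df <- as.data.frame(records)[, .tx_required_cols]
  df$cds_incomplete[df$cds_incomplete == "none"] <- NA
  for (cc in names(df)) {
    df[[cc]] <- as.character(df[[cc]])
    df[[cc]][is.na(df[[cc]])] <- "-"
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ------------------------------------------------------------------------
## cis-regulatory elements

.cisre_roles <- c("enhancer", "silencer", "promoter")

#' Construct a set of cis-regulatory elements
#'
#' @param name element identifiers (e.g. F3, F11, core promoter).
#' @param role one of `enhancer`, `silencer`, `promoter` per element.
#' @param start,end interval bounds (genomic 1-based inclusive, or any
#'   consistent coordinate space such as TSS-relative bases).
#' @return a data.frame of class `cis_re_set`.
#' @export
cis_re_set <- function(name, role, start, end) {
  if (any(!role %in% .cisre_roles))
    stop("role must be one of: ", paste(.cisre_roles, collapse = ", "))
  if (any(start > end)) stop("start > end in cis-RE interval")
  if (anyDuplicated(name)) stop("duplicate cis-RE names")
  df <- data.frame(name = as.character(name), role = as.character(role),
                   start = as.numeric(start), end = as.numeric(end),
                   stringsAsFactors = FALSE)
  class(df) <- c("cis_re_set", "data.frame")
  df
}

#' Write cis-regulatory elements as BED6
#'
#' Converts 1-based inclusive intervals to BED's 0-based half-open.
#'
#' @param x a [cis_re_set].
#' @param path output file.
#' @param chromosome chromosome name for the BED records.
#' @export
write_cis_re_bed <- function(x, path, chromosome = "chrX") {
  strand_col <- rep(".", nrow(x))
  df <- data.frame(chromosome, as.integer(x$start - 1), as.integer(x$end),
                   x$name, 0L, strand_col)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
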