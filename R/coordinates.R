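#' TSS-relative coordinate transforms
#'
#' Positions along the locus are expressed relative to the transcription
#' start site (TSS) of a gene, with positive values running 5' to 3' in the
#' transcription direction (into and beyond the gene body) and negative
#' values on the promoter side. For a minus-strand gene the relative
#' position of genomic coordinate `g` is therefore `TSS - g`; for a
#' plus-strand gene it is `g - TSS`.
#'
#' @param coord genomic position(s), 1-based.
#' @param gene a [gene_model] with a TSS anchor for `assembly`.
#' @param assembly assembly name (must be present in
#'   `gene$tss_by_assembly`).
#' @return signed distance(s) in bases; 0 at the TSS.
#' @examples
#' gm <- mecp2_gene_model()
#' genomic_to_relative(153363188, gm, "hg19")  # 0
#' @export
genomic_to_relative <- function(coord, gene, assembly) {
  tss <- .tss_anchor(gene, assembly)
  if (gene$strand == "-") tss - coord else coord - tss
}

#' @rdname genomic_to_relative
#' @param rel signed TSS-relative position(s) in bases.
#' @export
relative_to_genomic <- function(rel, gene, assembly) {
  tss <- .tss_anchor(gene, assembly)
  if (gene$strand == "-") tss - rel else tss + rel
}

.tss_anchor <- function(gene, assembly) {
  if (!assembly %in% names(gene$tss_by_assembly))
    stop("gene model has no TSS anchor for assembly '", assembly, "'")
  gene$tss_by_assembly[[assembly]]
}

#' Construct a set of TSS-relative intervals
#'
#' Fragment coordinates are given in signed kilobases relative to the TSS
#' (transcription-direction positive), the resolution at which kb-scale
#' segments are usually reported. Internal arithmetic is in integer bases
#' (kb values are expanded by x1000).
#'
#' @param label unique fragment labels (e.g. S1, A4, H6).
#' @param start_kb,end_kb interval bounds in kb, `start_kb <= end_kb`.
#' @param assembly assembly the anchors refer to.
#' @return data.frame of class `relative_intervals` with base-scale
#'   `start`/`end` columns (half-open internally: `[start, end)`).
#' @export
relative_intervals <- function(label, start_kb, end_kb, assembly = "hg19") {
  if (anyDuplicated(label)) stop("labels must be unique")
  swap <- start_kb > end_kb
  tmp <- start_kb[swap]; start_kb[swap] <- end_kb[swap]; end_kb[swap] <- tmp
  df <- data.frame(label = as.character(label),
                   start_kb = start_kb, end_kb = end_kb,
                   start = round(start_kb * 1000), end = round(end_kb * 1000),
                   assembly = assembly, stringsAsFactors = FALSE)
  class(df) <- c("relative_intervals", "data.frame")
  df
}

#' Classify a TSS-relative interval against the gene body
#'
#' The gene body occupies relative positions `[0, gene_length]`. An
#' interval entirely inside is `intragenic`; entirely at negative positions
#' is `upstream_of_tss`; entirely past the gene length is
#' `beyond_gene_3prime`; an interval crossing either boundary is
#' `spanning`.
#'
#' @param rel_interval a `relative_intervals` row set (or any data.frame
#'   with base-scale `start`/`end` columns).
#' @param gene a [gene_model] (its span defines the gene length).
#' @return character vector of classifications, one per interval.
#' @export
classify_position <- function(rel_interval, gene) {
  len <- gene_length(gene)
  s <- rel_interval$start
  e <- rel_interval$end
  ifelse(s >= 0 & e <= len, "intragenic",
  ifelse(e <= 0, "upstream_of_tss",
  ifelse(s >= len, "beyond_gene_3prime", "spanning")))
}
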