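#' Construct a fragment set
#'
#' A named collection of labelled intervals in one coordinate space,
#' either TSS-relative bases or genomic bases. Intervals are stored
#' half-open (`[start, end)`), the convention interval arithmetic is done
#' in; the kb-scale printed coordinates of a `relative_intervals` object
#' convert directly.
#'
#' @param name set identifier (e.g. `"S"`, `"A"`, `"H"`, `"F"`).
#' @param labels unique fragment labels.
#' @param start,end half-open interval bounds in bases.
#' @param space `"relative"` or `"genomic"`.
#' @param assembly assembly identifier.
#' @return data.frame of class `fragment_set`.
#' @export
fragment_set <- function(name, labels, start, end, space = "relative",
                         assembly = "hg19") {
  if (anyDuplicated(labels)) stop("fragment labels must be unique")
  if (any(end <= start)) stop("need end > start (half-open intervals)")
  df <- data.frame(label = as.character(labels), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  attr(df, "set_name") <- name
  attr(df, "space") <- space
  attr(df, "assembly") <- assembly
  class(df) <- c("fragment_set", "data.frame")
  df
}

#' @rdname fragment_set
#' @param ri a `relative_intervals` object (see [relative_intervals()]).
#' @export
as_fragment_set <- function(ri, name) {
  fragment_set(name, ri$label, ri$start, ri$end, space = "relative",
               assembly = ri$assembly[1L])
}

## both sets in a common space; convert relative -> genomic when one set
## is genomic and a gene anchor is available
.common_space <- function(a, b, gene = NULL) {
  sa <- attr(a, "space"); sb <- attr(b, "space")
  if (identical(sa, sb)) {
    if (sa == "genomic" &&
        !identical(attr(a, "assembly"), attr(b, "assembly")) &&
        is.null(gene))
      stop("fragment sets are on different assemblies; supply a gene ",
           "model with TSS anchors to convert")
    return(list(a = a, b = b))
  }
  if (is.null(gene))
    stop("fragment sets are in different coordinate spaces; supply a ",
         "gene model with TSS anchors to convert")
  conv <- function(x) {
    if (attr(x, "space") == "relative") {
      tss <- .tss_anchor(gene, attr(x, "assembly"))
      if (gene$strand == "-") {
        s <- tss - x$end + 1; e <- tss - x$start + 1
      } else {
        s <- tss + x$start; e <- tss + x$end
      }
      fragment_set(attr(x, "set_name"), x$label, s, e, space = "genomic",
                   assembly = attr(x, "assembly"))
    } else x
  }
  list(a = conv(a), b = conv(b))
}

#' Pairwise overlap matrix of two fragment sets
#'
#' @param set_a,set_b [fragment_set]s in the same coordinate space (or
#'   convertible via `gene`).
#' @param gene optional [gene_model] used to convert a relative set to
#'   genomic coordinates when the spaces differ.
#' @return list with matrices `overlap` (bases) and `jaccard`, rows =
#'   fragments of `set_a`, columns = fragments of `set_b`.
#' @export
overlap_matrix <- function(set_a, set_b, gene = NULL) {
  sp <- .common_space(set_a, set_b, gene)
  a <- sp$a; b <- sp$b
  ov <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j)
    pmax(0, pmin(a$end[i], b$end[j]) - pmax(a$start[i], b$start[j])))
  un <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j)
    (a$end[i] - a$start[i]) + (b$end[j] - b$start[j])) - ov
  jac <- ifelse(un > 0, ov / un, 0)
  dimnames(ov) <- dimnames(jac) <- list(a$label, b$label)
  list(overlap = ov, jaccard = jac)
}

#' Containment report of features within fragments
#'
#' For every fragment, classifies each feature as `contained` (feature
#' entirely within the fragment), `partial` (some overlap) or `none`.
#'
#' @param fragments,features [fragment_set]s.
#' @param gene optional [gene_model] for space conversion.
#' @param keep_none keep `none` rows (default drops them).
#' @return data.frame with `fragment`, `feature`, `relation`,
#'   `overlap` (bases), ordered by fragment position then feature
#'   position.
#' @export
containment_report <- function(fragments, features, gene = NULL,
                               keep_none = FALSE) {
  sp <- .common_space(fragments, features, gene)
  fr <- sp$a[order(sp$a$start), , drop = FALSE]
  fe <- sp$b[order(sp$b$start), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(fr))) for (j in seq_len(nrow(fe))) {
    ov <- max(0, min(fr$end[i], fe$end[j]) - max(fr$start[i], fe$start[j]))
    rel <- if (ov <= 0) "none"
    else if (fe$start[j] >= fr$start[i] && fe$end[j] <= fr$end[i]) "contained"
    else "partial"
    if (rel == "none" && !keep_none) next
    rows[[length(rows) + 1L]] <- data.frame(fragment = fr$label[i],
                                            feature = fe$label[j],
                                            relation = rel, overlap = ov,
                                            stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(fragment = character(0), feature = character(0),
                      relation = character(0), overlap = numeric(0)))
  do.call(rbind, rows)
}

#' Intersect two fragment sets
#'
#' Returns the intervals of mutual overlap of at least `min_overlap`
#' bases, labelled `"<a>∩<b>"`.
#'
#' @param set_a,set_b [fragment_set]s.
#' @param min_overlap minimum overlap in bases.
#' @param gene optional [gene_model] for space conversion.
#' @return a [fragment_set] of the intersections (possibly empty).
#' @export
intersect_sets <- function(set_a, set_b, min_overlap = 1, gene = NULL) {
  sp <- .common_space(set_a, set_b, gene)
  a <- sp$a; b <- sp$b
  labs <- character(0); ss <- numeric(0); ee <- numeric(0)
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    s <- max(a$start[i], b$start[j]); e <- min(a$end[i], b$end[j])
    if (e - s >= min_overlap) {
      labs <- c(labs, paste0(a$label[i], "\u2229", b$label[j]))
      ss <- c(ss, s); ee <- c(ee, e)
    }
  }
  nm <- paste0(attr(a, "set_name"), "\u2229", attr(b, "set_name"))
  if (!length(labs))
    return(fragment_set(nm, character(0), numeric(0), numeric(0),
                        space = attr(a, "space"),
                        assembly = attr(a, "assembly")))
  fragment_set(nm, make.unique(labs), ss, ee, space = attr(a, "space"),
               assembly = attr(a, "assembly"))
}

#' Write a co-localization report
#'
#' Plain-text "includes / aligns with / overlaps" phrasing per fragment.
#'
#' @param report output of [containment_report()].
#' @param path output file (or `""` for stdout).
#' @export
write_coloc_report <- function(report, path = "") {
  lines <- character(0)
  for (fr in unique(report$fragment)) {
    rr <- report[report$fragment == fr, , drop = FALSE]
    contained <- rr$feature[rr$relation == "contained"]
    partial <- rr$feature[rr$relation == "partial"]
    txt <- paste0(fr, ":")
    if (length(contained))
      txt <- paste0(txt, " includes ", paste(contained, collapse = ", "), ".")
    if (length(partial))
      txt <- paste0(txt, " overlaps ", paste(partial, collapse = ", "), ".")
    if (!length(contained) && !length(partial))
      txt <- paste0(txt, " no co-localized features.")
    lines <- c(lines, txt)
  }
  if (nzchar(path)) writeLines(lines, path) else writeLines(lines)
  invisible(lines)
}
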