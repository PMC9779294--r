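#' Read a functional-domain annotation table
#'
#' TSV with columns `name`, `ref_isoform`, `start`, `end`, `source`
#' (1-based inclusive protein coordinates on the reference isoform).
#' Lines starting with `#` carry provenance comments.
#'
#' @param path TSV file.
#' @return data.frame of class `functional_domains`.
#' @export
read_domain_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("name", "ref_isoform", "start", "end", "source")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("domain table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(df$start < 1 | df$start > df$end))
    stop("invalid domain coordinates (need 1 <= start <= end)")
  class(df) <- c("functional_domains", "data.frame")
  df
}

#' Classify the completeness of a functional domain in an isoform
#'
#' Projects a reference-coordinate domain through a pairwise alignment and
#' classifies what part of it the query isoform carries. A reference
#' position counts as matched only when aligned to an identical query
#' residue inside an anchored run (>= `min_anchor` consecutive identical
#' columns); this treats substitution-free presence as present and
#' discounts chance identities inside divergent blocks.
#'
#' Categories: `complete` (all positions matched), `missing` (coverage at
#' or below `missing_threshold`), `n_incomplete` / `c_incomplete` /
#' `n_and_c_incomplete` (unmatched positions confined to a prefix and/or
#' suffix), `internal_gap` (an unmatched interior run with matched
#' flanks; prefix/suffix flags preserved), and `alternative_n_terminus`
#' (the unmatched prefix is aligned against residues of a different
#' N-terminus rather than simply absent).
#'
#' @param aln a `pairwise_alignment` whose reference is the domain's
#'   reference isoform.
#' @param domain one-row data.frame (or list) with `name`, `start`, `end`.
#' @param missing_threshold coverage at or below which a fragmentary match
#'   is reported as missing (default 0.1).
#' @param min_anchor anchored-run length for matched positions.
#' @return object of class `domain_status`: list with `category`, `flags`,
#'   `coverage`, `matched_span`.
#' @export
classify_domain <- function(aln, domain, missing_threshold = 0.1,
                            min_anchor = 6L) {
  ref_len <- sum(!is.na(aln$column_map[, "ref"]))
  if (domain$start < 1 || domain$end > ref_len)
    stop("domain '", domain$name, "' outside the reference range 1..",
         ref_len)
  matched <- matched_ref_positions(aln, min_anchor = min_anchor)
  dom <- domain$start:domain$end
  m_local <- which(dom %in% matched)
  st <- .status_from_matched(m_local, length(dom), missing_threshold,
                             offset = domain$start - 1L)
  if (st$category == "n_incomplete") {
    ## prefix absent vs replaced: if the unmatched prefix positions are the
    ## ones consumed by a leading divergent block that carries query
    ## residues, the isoform brings a different N-terminus there
    altn <- .alt_n_block(aln, min_anchor)
    unmatched_ref <- setdiff(dom, dom[m_local])
    if (altn$has_query_residues && length(unmatched_ref) &&
        all(unmatched_ref %in% altn$ref_positions))
      st$category <- "alternative_n_terminus"
  }
  st
}

## leading divergent block: columns before the first anchored identical
## column; reports the ref positions it consumes and whether the query
## contributes residues there (an alternative N-terminus)
.alt_n_block <- function(aln, min_anchor) {
  a <- strsplit(aln$aligned_ref, "")[[1L]]
  b <- strsplit(aln$aligned_query, "")[[1L]]
  ident <- a == b & a != "-"
  runs <- rle(ident)
  runs$values <- runs$values & runs$lengths >= min_anchor
  anchored <- inverse.rle(runs)
  first <- which(anchored)[1L]
  if (is.na(first) || first == 1L)
    return(list(ref_positions = integer(0), has_query_residues = FALSE))
  pre <- seq_len(first - 1L)
  list(ref_positions = stats::na.omit(aln$column_map[pre, "ref"]),
       has_query_residues = any(b[pre] != "-"))
}

## matched: sorted local positions within 1..len
.status_from_matched <- function(matched, len, missing_threshold = 0.1,
                                 offset = 0L) {
  matched <- sort(unique(matched))
  coverage <- length(matched) / len
  span <- if (length(matched))
    c(first = matched[1L] + offset, last = matched[length(matched)] + offset)
  else c(first = NA_integer_, last = NA_integer_)
  unmatched <- setdiff(seq_len(len), matched)
  flags <- c(prefix = FALSE, interior = FALSE, suffix = FALSE)
  if (length(unmatched) && length(matched)) {
    flags["prefix"] <- unmatched[1L] == 1L && matched[1L] > 1L
    flags["suffix"] <- unmatched[length(unmatched)] == len
    interior <- unmatched[unmatched > matched[1L] &
                            unmatched < matched[length(matched)]]
    flags["interior"] <- length(interior) > 0L
  }
  category <-
    if (coverage == 1) "complete"
    else if (coverage <= missing_threshold) "missing"
    else if (flags["interior"]) "internal_gap"
    else if (flags["prefix"] && flags["suffix"]) "n_and_c_incomplete"
    else if (flags["prefix"]) "n_incomplete"
    else "c_incomplete"
  structure(list(category = category, flags = flags, coverage = coverage,
                 matched_span = span), class = "domain_status")
}

#' @export
print.domain_status <- function(x, ...) {
  cat("domain_status:", x$category,
      sprintf("(coverage %.2f)", x$coverage), "\n")
  invisible(x)
}

#' Render a domain status in the summary-table vocabulary
#'
#' @param status a `domain_status` (or its category string for the simple
#'   cases).
#' @return a single cell string such as `"✓"`, `"-"`,
#'   `"N-term. incompl."` or `"C-term. incompl, missing fragment inside"`.
#' @export
render_status <- function(status) {
  if (is.character(status)) status <- list(category = status,
                                           flags = c(prefix = FALSE,
                                                     interior = FALSE,
                                                     suffix = FALSE))
  cat_ <- status$category
  if (cat_ == "complete") return("\u2713")
  if (cat_ == "missing") return("-")
  if (cat_ == "alternative_n_terminus") return("Possible different N-terminus")
  if (cat_ == "n_incomplete") return("N-term. incompl.")
  if (cat_ == "c_incomplete") return("C-term. incompl.")
  if (cat_ == "n_and_c_incomplete") return("N-term. and C-term. incompl.")
  ## internal_gap, with whatever terminal truncation accompanies it
  pre <- status$flags[["prefix"]]; suf <- status$flags[["suffix"]]
  if (pre && suf) return("N-term. and C-term. incompl, missing fragment inside")
  if (suf) return("C-term. incompl, missing fragment inside")
  if (pre) return("N-term. incompl, missing fragment inside")
  "missing fragment inside"
}

#' Per-exon presence status of an isoform
#'
#' Uses the exon-peptide positions matched by [exon_provenance()] and the
#' full exon peptide lengths to classify each coding exon's contribution:
#' `present`, `n_incomplete`, `c_incomplete`, `absent`, or (for
#' fragmented contributions) an internal-gap status.
#'
#' @param provenance a `provenance_track`.
#' @param exon_peptides the translated exon peptides given to
#'   [exon_provenance()].
#' @param missing_threshold coverage at or below which an exon is absent.
#' @return named list of `domain_status` objects, one per coding exon.
#' @export
exon_presence <- function(provenance, exon_peptides, missing_threshold = 0.1) {
  out <- list()
  for (k in seq_along(exon_peptides)) {
    if (!nzchar(exon_peptides[k])) next
    len <- nchar(exon_peptides[k])
    st <- .status_from_matched(provenance$exon_matches[[k]], len,
                               missing_threshold)
    if (st$category == "complete") st$category <- "present"
    else if (st$category == "missing") st$category <- "absent"
    out[[paste0("exon", k)]] <- st
  }
  out
}

#' Build the isoform-by-domain completeness table
#'
#' Aligns every isoform to the domain-bearing reference isoform,
#' classifies every functional domain, and adds per-exon presence rows
#' from exon provenance. Each isoform is also aligned to every reference
#' in `references` and the best-scoring one is reported as its matching
#' reference (isoforms with an E1-style N-terminus match the E1-style
#' reference); domain classification itself is always performed on the
#' alignment to the domain-bearing reference, where the coordinates live.
#'
#' @param isoforms named character vector of isoform sequences.
#' @param domains a `functional_domains` table (single `ref_isoform`).
#' @param references named character vector of reference isoform
#'   sequences; must include the domain table's `ref_isoform`.
#' @param exon_peptides translated exon peptides in transcription order
#'   (empty string for non-coding exons).
#' @param missing_threshold,min_anchor see [classify_domain()].
#' @param params alignment parameters.
#' @return object of class `domain_table`: list with `cells` (character
#'   matrix, rows = exon and domain names, columns = isoforms, in the
#'   summary vocabulary), `status` (list matrix of `domain_status`),
#'   `matching_ref` (named character), `scores`.
#' @export
build_domain_table <- function(isoforms, domains, references, exon_peptides,
                               missing_threshold = 0.1, min_anchor = 6L,
                               params = align_params()) {
  ref_name <- unique(domains$ref_isoform)
  if (length(ref_name) != 1L)
    stop("domain table must use a single reference isoform")
  if (!ref_name %in% names(references))
    stop("references must include the domain reference '", ref_name, "'")
  ref_seq <- stats::setNames(references[[ref_name]], ref_name)

  exon_rows <- paste0("exon", which(nzchar(exon_peptides)))
  rows <- c(exon_rows, domains$name)
  cells <- matrix(NA_character_, length(rows), length(isoforms),
                  dimnames = list(rows, names(isoforms)))
  status <- matrix(list(), length(rows), length(isoforms),
                   dimnames = list(rows, names(isoforms)))
  matching_ref <- character(length(isoforms))
  names(matching_ref) <- names(isoforms)
  scores <- matching_ref

  for (iso in names(isoforms)) {
    q <- stats::setNames(isoforms[[iso]], iso)
    aln <- global_align(ref_seq, q, params)
    ## best-scoring reference (reported, not used for classification)
    best <- vapply(names(references), function(r)
      global_align(stats::setNames(references[[r]], r), q, params)$score,
      numeric(1))
    matching_ref[iso] <- names(which.max(best))
    scores[iso] <- max(best)
    prov <- exon_provenance(q, exon_peptides, min_anchor)
    ep <- exon_presence(prov, exon_peptides, missing_threshold)
    for (rn in names(ep)) {
      status[[rn, iso]] <- ep[[rn]]
      cells[rn, iso] <- render_status(.as_domain_vocab(ep[[rn]]))
    }
    for (d in seq_len(nrow(domains))) {
      st <- classify_domain(aln, domains[d, ], missing_threshold, min_anchor)
      status[[domains$name[d], iso]] <- st
      cells[domains$name[d], iso] <- render_status(st)
    }
  }
  structure(list(cells = cells, status = status,
                 matching_ref = matching_ref, scores = scores),
            class = "domain_table")
}

## exon statuses use present/absent; render with the same vocabulary
.as_domain_vocab <- function(st) {
  st$category <- switch(st$category, present = "complete",
                        absent = "missing", st$category)
  st
}

#' @export
print.domain_table <- function(x, ...) {
  print(x$cells, quote = FALSE)
  invisible(x)
}

#' Write a domain table as TSV
#'
#' @param x a `domain_table`.
#' @param path output file.
#' @export
write_domain_table <- function(x, path) {
  df <- data.frame(feature = rownames(x$cells), x$cells,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compare a computed domain table with an expected transcription
#'
#' @param table a `domain_table`.
#' @param expected_path TSV fixture: first column `feature`, remaining
#'   columns the expected cells per isoform.
#' @return data.frame of discrepancies (zero rows when the tables agree
#'   cell-for-cell); attributes `n_cells` and `n_match`.
#' @export
compare_domain_table <- function(table, expected_path) {
  exp_df <- utils::read.delim(expected_path, sep = "\t", comment.char = "#",
                              check.names = FALSE, stringsAsFactors = FALSE)
  rn <- exp_df[[1L]]
  exp_m <- as.matrix(exp_df[, -1L, drop = FALSE])
  rownames(exp_m) <- rn
  disc <- list()
  for (r in rownames(exp_m)) for (cc in colnames(exp_m)) {
    if (!r %in% rownames(table$cells) || !cc %in% colnames(table$cells)) {
      disc[[length(disc) + 1L]] <- data.frame(feature = r, isoform = cc,
                                              expected = exp_m[r, cc],
                                              computed = NA_character_)
      next
    }
    if (!identical(exp_m[r, cc], table$cells[r, cc]))
      disc[[length(disc) + 1L]] <- data.frame(feature = r, isoform = cc,
                                              expected = exp_m[r, cc],
                                              computed = table$cells[r, cc])
  }
  out <- if (length(disc)) do.call(rbind, disc)
  else data.frame(feature = character(0), isoform = character(0),
                  expected = character(0), computed = character(0))
  attr(out, "n_cells") <- length(exp_m)
  attr(out, "n_match") <- length(exp_m) - nrow(out)
  out
}
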