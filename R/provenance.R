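#' Per-residue exon provenance of an isoform
#'
#' Labels every residue of an isoform with the exon whose translated
#' peptide it matches, by locating maximal exact matches of at least
#' `min_anchor` residues between the isoform and each exon peptide.
#' Overlapping candidate labels are resolved by longest match first, then
#' by the 5'-most exon, then by position. Residues left unlabeled form the
#' `novel` segments (e.g. alternative C-termini translated from introns or
#' from an exon in a different frame).
#'
#' @param isoform named length-1 character vector (amino-acid sequence).
#' @param exon_peptides character vector of translated exon peptides in
#'   transcription order; empty strings mark non-coding exons.
#' @param min_anchor minimum exact-match length for a label (default 6;
#'   shorter matches are too ambiguous).
#' @return object of class `provenance_track`: list with `isoform_id`,
#'   `labels` (per-residue, `"exon<k>"` or `"novel"`), `novel_segments`
#'   (matrix of maximal novel runs in isoform coordinates) and
#'   `exon_matches` (per exon, the matched exon-peptide positions).
#' @export
exon_provenance <- function(isoform, exon_peptides, min_anchor = 6L) {
  id <- names(isoform) %||% "isoform"
  s <- .check_aa(unname(isoform))
  n <- length(s)
  cand <- list()
  for (k in seq_along(exon_peptides)) {
    if (!nzchar(exon_peptides[k])) next
    p <- strsplit(exon_peptides[k], "")[[1L]]
    mm <- .maximal_matches(s, p, min_anchor)
    if (nrow(mm))
      cand[[length(cand) + 1L]] <- cbind(mm, exon = rep(k, nrow(mm)))
  }
  cand <- do.call(rbind, cand)
  labels <- rep("novel", n)
  exon_matches <- lapply(exon_peptides, function(.) integer(0))
  if (!is.null(cand) && nrow(cand)) {
    o <- order(-cand[, "len"], cand[, "exon"], cand[, "iso_start"])
    cand <- cand[o, , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      idx <- cand[r, "iso_start"]:cand[r, "iso_end"]
      free <- labels[idx] == "novel"
      if (!any(free)) next
      k <- cand[r, "exon"]
      labels[idx[free]] <- paste0("exon", k)
      pep_pos <- cand[r, "pep_start"] + (idx[free] - cand[r, "iso_start"])
      exon_matches[[k]] <- sort(unique(c(exon_matches[[k]], pep_pos)))
    }
  }
  novel <- .runs(labels == "novel")
  structure(list(isoform_id = id, labels = labels,
                 novel_segments = novel, exon_matches = exon_matches),
            class = "provenance_track")
}

## maximal exact common substrings of s and p with length >= min_len,
## reported as (iso_start, iso_end, pep_start, pep_end, len)
.maximal_matches <- function(s, p, min_len) {
  n <- length(s); m <- length(p)
  out <- list()
  for (d in (-(m - 1L)):(n - 1L)) {   # diagonal offset: iso_pos - pep_pos
    i0 <- max(1L, 1L + d); j0 <- i0 - d
    len <- min(n - i0, m - j0) + 1L
    if (len < min_len) next
    eq <- s[i0:(i0 + len - 1L)] == p[j0:(j0 + len - 1L)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values & r$lengths >= min_len)
    for (w in keep) {
      out[[length(out) + 1L]] <- c(iso_start = i0 + starts[w] - 1L,
                                   iso_end = i0 + ends[w] - 1L,
                                   pep_start = j0 + starts[w] - 1L,
                                   pep_end = j0 + ends[w] - 1L,
                                   len = r$lengths[w])
    }
  }
  if (!length(out))
    return(matrix(integer(0), 0, 5,
                  dimnames = list(NULL, c("iso_start", "iso_end",
                                          "pep_start", "pep_end", "len"))))
  do.call(rbind, out)
}

.runs <- function(flag) {
  if (!any(flag)) return(matrix(integer(0), 0, 2,
                                dimnames = list(NULL, c("start", "end"))))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' @export
print.provenance_track <- function(x, ...) {
  cat("provenance_track:", x$isoform_id, "-", length(x$labels), "residues\n")
  print(table(x$labels))
  if (nrow(x$novel_segments)) {
    cat("novel segments:\n")
    print(x$novel_segments)
  }
  invisible(x)
}

#' Count distinctive terminal residues of two isoforms
#'
#' Two isoforms that share everything but one terminus (such as the two
#' established MeCP2 splice isoforms, which differ only at their
#' N-termini) are compared by their longest common suffix (N-terminal
#' difference) or longest common prefix (C-terminal difference): the
#' residues outside the shared part are each isoform's distinctive
#' residues. The larger of the two shared lengths decides which terminus
#' differs.
#'
#' @param iso_a,iso_b amino-acid strings (optionally named).
#' @return list with `a`, `b` (distinctive residue counts) and `terminus`
#'   (`"N"` or `"C"`).
#' @examples
#' terminal_diff("XXAB", "YAB")  # 2, 1, N
#' @export
terminal_diff <- function(iso_a, iso_b) {
  a <- .check_aa(unname(iso_a)); b <- .check_aa(unname(iso_b))
  suf <- .common_terminal(a, b, from_end = TRUE)
  pre <- .common_terminal(a, b, from_end = FALSE)
  if (suf == 0L && pre == 0L)
    stop("isoforms share no common terminus")
  if (suf >= pre)
    list(a = length(a) - suf, b = length(b) - suf, terminus = "N")
  else
    list(a = length(a) - pre, b = length(b) - pre, terminus = "C")
}

#' Length of the shared terminal fragment of two isoforms
#'
#' @param iso_a,iso_b amino-acid strings.
#' @param terminus `"N"` (longest common prefix) or `"C"` (longest common
#'   suffix).
#' @return integer residue count (0 when the termini differ immediately).
#' @export
shared_terminal_fragment <- function(iso_a, iso_b, terminus = c("N", "C")) {
  terminus <- match.arg(terminus)
  a <- .check_aa(unname(iso_a)); b <- .check_aa(unname(iso_b))
  .common_terminal(a, b, from_end = terminus == "C")
}

.common_terminal <- function(a, b, from_end) {
  if (from_end) { a <- rev(a); b <- rev(b) }
  k <- min(length(a), length(b))
  if (k == 0L) return(0L)
  neq <- which(a[seq_len(k)] != b[seq_len(k)])
  if (!length(neq)) k else neq[1L] - 1L
}

#' Locate a novel peptide fragment in the gene locus
#'
#' Searches all six reading-frame translations of the locus DNA for the
#' best ungapped match of a peptide (exact scan with per-offset Hamming
#' identity; the fragments of interest are contiguous translations, so no
#' gaps are needed). When the best identity reaches `min_identity`, the
#' hit is mapped back to genomic coordinates and the overlapped gene
#' feature (exon or intron index) is reported; otherwise the feature is
#' `none`. Ties are broken by the 5'-most genomic start.
#'
#' @param peptide amino-acid string, length >= 6.
#' @param gene a [gene_model] whose exon coordinates index into `dna`.
#' @param dna plus-strand locus DNA (position 1 = genomic coordinate 1 of
#'   the synthetic chromosome).
#' @param min_identity identity fraction required to assign a feature.
#' @return list of class `fragment_origin`: `locus_feature` (`"exon"`,
#'   `"intron"` or `"none"`), `feature_index`, `frame` (0-2 plus strand,
#'   3-5 minus strand), `match_identity`, `genomic_start`, `genomic_end`.
#' @export
locate_novel_fragment <- function(peptide, gene, dna, min_identity = 0.9) {
  pep <- .check_aa(unname(peptide))
  if (length(pep) < 6L) stop("peptide must be at least 6 residues")
  L <- nchar(dna)
  frames <- six_frame_translation(dna)
  best <- list(identity = -1, start = Inf)
  k <- length(pep)
  for (f in 0:5) {
    prot <- strsplit(frames[f + 1L], "")[[1L]]
    W <- length(prot) - k + 1L
    if (W < 1L) next
    hits <- integer(W)
    for (p in seq_len(k))
      hits <- hits + (prot[p:(p + W - 1L)] == pep[p])
    ident <- hits / k
    ## genomic start (5'-most coordinate) of each window
    w <- seq_len(W)
    if (f < 3L) {
      gstart <- f + 3 * (w - 1) + 1
      gend <- gstart + 3 * k - 1
    } else {
      off <- f - 3L
      rc_start <- off + 3 * (w - 1) + 1
      gend <- L - rc_start + 1
      gstart <- gend - 3 * k + 1
    }
    o <- order(-ident, gstart)
    top <- o[1L]
    if (ident[top] > best$identity ||
        (ident[top] == best$identity && gstart[top] < best$start)) {
      best <- list(identity = ident[top], start = gstart[top],
                   end = gend[top], frame = f)
    }
  }
  feature <- list(type = "none", index = NA_integer_)
  if (best$identity >= min_identity)
    feature <- .overlapped_feature(gene, best$start, best$end)
  structure(list(locus_feature = feature$type, feature_index = feature$index,
                 frame = best$frame, match_identity = best$identity,
                 genomic_start = best$start, genomic_end = best$end),
            class = "fragment_origin")
}

#' Six-frame translation of a DNA sequence
#'
#' @param dna DNA string (A/C/G/T/N). Stops translate to `*`.
#' @return character vector of 6 protein strings (frames +0,+1,+2 then the
#'   three reverse-complement frames).
#' @export
six_frame_translation <- function(dna) {
  fwd <- Biostrings::DNAString(dna)
  rev <- Biostrings::reverseComplement(fwd)
  tr <- function(x, off) {
    len <- (length(x) - off) %/% 3L * 3L
    if (len < 3L) return("")
    as.character(Biostrings::translate(Biostrings::subseq(x, off + 1L, off + len),
                                       if.fuzzy.codon = "X"))
  }
  c(tr(fwd, 0L), tr(fwd, 1L), tr(fwd, 2L),
    tr(rev, 0L), tr(rev, 1L), tr(rev, 2L))
}

## feature (exon/intron in transcription order) with the largest overlap
.overlapped_feature <- function(gene, start, end) {
  ex <- gene$exons
  n <- nrow(ex)
  feats <- data.frame(type = "exon", index = seq_len(n),
                      start = ex[, 1L], end = ex[, 2L])
  if (n > 1L) {
    for (k in seq_len(n - 1L)) {
      lo <- min(ex[k, ], ex[k + 1L, ]); hi <- max(ex[k, ], ex[k + 1L, ])
      ## gap between exon k and k+1 in transcription order
      gap_lo <- min(ex[k, 2L], ex[k + 1L, 2L]) + 1
      gap_hi <- max(ex[k, 1L], ex[k + 1L, 1L]) - 1
      if (gap_lo <= gap_hi)
        feats <- rbind(feats, data.frame(type = "intron", index = k,
                                         start = gap_lo, end = gap_hi))
    }
  }
  ov <- pmax(0, pmin(feats$end, end) - pmax(feats$start, start) + 1)
  if (all(ov == 0)) return(list(type = "none", index = NA_integer_))
  top <- which.max(ov)
  list(type = feats$type[top], index = feats$index[top])
}
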