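# Independent oracles used across the suite.

# Exhaustive enumeration of all monotone alignments with affine gap
# scoring (gap of length k costs go + k*ge). Exponential; only for short
# sequences.
bf_align_score <- function(a, b, params = align_params()) {
  sub <- params$substitution
  go <- params$gap_open
  ge <- params$gap_extend
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, sub[av[i], bv[j]] + rec(i + 1L, j + 1L, "M"))
    if (i <= n)
      best <- max(best, ge + (if (last == "X") 0 else go) +
                    rec(i + 1L, j, "X"))
    if (j <= m)
      best <- max(best, ge + (if (last == "Y") 0 else go) +
                    rec(i, j + 1L, "Y"))
    best
  }
  rec(1L, 1L, "start")
}

random_aa <- function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]],
                                      n, replace = TRUE), collapse = "")

# Quadratic-scan interval overlap oracle on half-open intervals.
bf_overlap_matrix <- function(a, b) {
  ov <- matrix(0, nrow(a), nrow(b))
  jac <- ov
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    o <- max(0, min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]))
    u <- (a$end[i] - a$start[i]) + (b$end[j] - b$start[j]) - o
    ov[i, j] <- o
    jac[i, j] <- if (u > 0) o / u else 0
  }
  list(overlap = ov, jaccard = jac)
}

random_fragment_set <- function(name, n, span = 100000) {
  s <- sort(sample.int(span, n))
  w <- sample.int(2000, n)
  fragment_set(name, paste0(name, seq_len(n)), s, s + w, space = "genomic")
}

# Union Jaccard between calls (data.frame start/end, 1-based inclusive)
# and a list of truth intervals list(start=, end=) or c(start, end).
union_jaccard <- function(calls, truth) {
  tir <- IRanges::reduce(do.call(c, lapply(truth, function(h) {
    if (is.list(h)) IRanges::IRanges(h$start, h$end)
    else IRanges::IRanges(h[1], h[2])
  })))
  if (!nrow(calls)) return(0)
  cir <- IRanges::reduce(IRanges::IRanges(calls$start, calls$end))
  sum(IRanges::width(IRanges::intersect(cir, tir))) /
    sum(IRanges::width(IRanges::union(cir, tir)))
}

called_length <- function(calls) {
  if (!nrow(calls)) 0 else sum(calls$end - calls$start + 1)
}

ext_fixture <- function(f) system.file("extdata", f, package = "mecp2scan",
                                       mustWork = TRUE)
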