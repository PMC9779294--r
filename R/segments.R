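#' Segment-caller parameters
#'
#' Formalizes the visual identification of consistent segments in browser
#' tracks as a reproducible rule. Defaults: 200-bp bins; a bin is
#' enriched in a track when it reaches that track's 0.9 signal quantile
#' over the region (per-track quantiles absorb depth differences between
#' samples; the 0.9 cut keeps the consensus false-call rate to a few bins
#' per 100 kb on Poisson backgrounds while kb-scale enriched segments
#' clear it comfortably); a bin is consensus-enriched when enriched in at least 70% of
#' tracks ("most of the studied tissues"); consensus bins are merged
#' across gaps up to 2 kb (the segments of interest are kb-scale) and
#' calls shorter than 500 bp are dropped. Hypomethylated regions are runs
#' of at least 3 bins with mean methylation fraction at or below 0.3.
#'
#' @param bin_size bin width, bases.
#' @param enrich_quantile per-track enrichment quantile in (0,1).
#' @param consensus_fraction fraction of tracks required, in (0,1].
#' @param merge_gap maximum gap merged, bases.
#' @param min_length minimum segment length, bases.
#' @param hmr_threshold methylation fraction at or below which a bin is
#'   hypomethylated.
#' @param hmr_min_bins minimum run length (bins) for an HMR.
#' @return list of class `caller_params`.
#' @export
caller_params <- function(bin_size = 200, enrich_quantile = 0.9,
                          consensus_fraction = 0.7, merge_gap = 2000,
                          min_length = 500, hmr_threshold = 0.3,
                          hmr_min_bins = 3L) {
  stopifnot(bin_size > 0, merge_gap >= 0, min_length > 0, hmr_min_bins >= 1,
            enrich_quantile > 0, enrich_quantile < 1,
            consensus_fraction > 0, consensus_fraction <= 1,
            hmr_threshold > 0, hmr_threshold < 1)
  structure(list(bin_size = bin_size, enrich_quantile = enrich_quantile,
                 consensus_fraction = consensus_fraction,
                 merge_gap = merge_gap, min_length = min_length,
                 hmr_threshold = hmr_threshold,
                 hmr_min_bins = as.integer(hmr_min_bins)),
            class = "caller_params")
}

## per-track mean signal on a bin grid; uncovered stretches count as 0
.bin_means <- function(track, starts, ends, warn_gaps = TRUE) {
  bw <- ends - starts + 1
  ir_bins <- IRanges::IRanges(starts, ends)
  ir_trk <- IRanges::IRanges(track$start, track$end)
  hits <- IRanges::findOverlaps(ir_bins, ir_trk)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(ir_bins[q], ir_trk[s]))
  sums <- numeric(length(starts))
  agg <- tapply(track$value[s] * ov, q, sum)
  sums[as.integer(names(agg))] <- agg
  covered <- numeric(length(starts))
  cagg <- tapply(ov, q, sum)
  covered[as.integer(names(cagg))] <- cagg
  if (warn_gaps && any(covered < bw))
    warning("track ", attr(track, "sample_id"),
            ": missing coverage in ", sum(covered < bw),
            " bin(s); treated as 0", call. = FALSE)
  sums / bw
}

.check_region <- function(region, params) {
  if (length(region) != 2L || region[2] < region[1])
    stop("empty or invalid region")
  if (params$bin_size > region[2] - region[1] + 1)
    stop("bin_size larger than the region")
  starts <- seq(region[1], region[2], by = params$bin_size)
  list(starts = starts, ends = pmin(starts + params$bin_size - 1, region[2]))
}

#' Call consensus-enriched segments from multi-sample signal tracks
#'
#' Per track, bin means are computed on a fixed grid over the region and
#' a bin is enriched when its value reaches that track's
#' `enrich_quantile` within the region (and is positive, so a flat zero
#' track enriches nothing). Bins enriched in at least
#' `consensus_fraction` of tracks are merged across gaps up to
#' `merge_gap`; segments shorter than `min_length` are dropped and
#' labelled in transcription-direction order.
#'
#' @param tracks list of [signal_track]s.
#' @param region `c(start, end)` genomic interval (1-based inclusive).
#' @param params a [caller_params].
#' @param gene optional [gene_model]; a minus-strand gene labels segments
#'   right to left. Default labelling is left to right.
#' @param label_prefix prefix for segment labels (e.g. `"S"`, `"A"`).
#' @return data.frame of class `segment_calls`: `label`, `start`, `end`
#'   (1-based inclusive), `support` (mean consensus fraction over the
#'   segment's bins), `mean_signal`, `n_tracks`.
#' @export
call_consensus_segments <- function(tracks, region, params = caller_params(),
                                    gene = NULL, label_prefix = "S") {
  if (!length(tracks)) stop("need at least one track")
  grid <- .check_region(region, params)
  vals <- vapply(tracks, .bin_means, numeric(length(grid$starts)),
                 starts = grid$starts, ends = grid$ends)
  vals <- matrix(vals, ncol = length(tracks))
  enriched <- vapply(seq_along(tracks), function(t) {
    q <- stats::quantile(vals[, t], params$enrich_quantile, names = FALSE)
    vals[, t] >= q & vals[, t] > 0
  }, logical(nrow(vals)))
  enriched <- matrix(enriched, ncol = length(tracks))
  frac <- rowMeans(enriched)
  cons <- frac >= params$consensus_fraction
  segs <- .bins_to_segments(cons, grid, params)
  if (!nrow(segs)) return(.empty_calls(length(tracks)))
  support <- mean_signal <- numeric(nrow(segs))
  for (i in seq_len(nrow(segs))) {
    inb <- grid$starts >= segs$start[i] & grid$ends <= segs$end[i]
    support[i] <- mean(frac[inb])
    mean_signal[i] <- mean(vals[inb, ])
  }
  .label_calls(data.frame(start = segs$start, end = segs$end,
                          support = support, mean_signal = mean_signal,
                          n_tracks = length(tracks)),
               gene, label_prefix)
}

.bins_to_segments <- function(flag, grid, params) {
  if (!any(flag)) return(data.frame(start = numeric(0), end = numeric(0)))
  ir <- IRanges::reduce(IRanges::IRanges(grid$starts[flag], grid$ends[flag]),
                        min.gapwidth = params$merge_gap + 1)
  ir <- ir[IRanges::width(ir) >= params$min_length]
  data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
}

.label_calls <- function(df, gene, prefix) {
  o <- if (!is.null(gene) && gene$strand == "-") order(-df$start)
       else order(df$start)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df <- cbind(label = paste0(prefix, seq_len(nrow(df))), df,
              stringsAsFactors = FALSE)
  class(df) <- c("segment_calls", "data.frame")
  df
}

.empty_calls <- function(n_tracks) {
  df <- data.frame(label = character(0), start = numeric(0),
                   end = numeric(0), support = numeric(0),
                   mean_signal = numeric(0), n_tracks = integer(0))
  class(df) <- c("segment_calls", "data.frame")
  df
}

#' Call per-sample hypomethylated regions
#'
#' Per sample, maximal runs of at least `hmr_min_bins` consecutive bins
#' whose mean methylation fraction is at or below `hmr_threshold`, merged
#' across gaps up to `merge_gap`. Bins without coverage are not called.
#'
#' @param tracks list of [methylation_track]s.
#' @param region `c(start, end)` interval.
#' @param params a [caller_params].
#' @return named list (one element per sample) of data.frames with
#'   `start`, `end`.
#' @export
call_hmrs <- function(tracks, region, params = caller_params()) {
  if (!length(tracks)) stop("need at least one track")
  grid <- .check_region(region, params)
  lapply(stats::setNames(tracks,
                         vapply(tracks, attr, "", "sample_id")),
         function(tr) {
    if (any(tr$value < 0 | tr$value > 1))
      stop("methylation fractions outside [0, 1]")
    m <- .bin_means(tr, grid$starts, grid$ends, warn_gaps = FALSE)
    ir_trk <- IRanges::IRanges(tr$start, tr$end)
    ir_bins <- IRanges::IRanges(grid$starts, grid$ends)
    covered <- IRanges::overlapsAny(ir_bins, ir_trk)
    low <- covered & m <= params$hmr_threshold
    runs <- .runs(low)
    if (!nrow(runs))
      return(data.frame(start = numeric(0), end = numeric(0)))
    ## merge across small gaps first, then require enough low bins per
    ## merged region (so a single noisy edge bin cannot clip a region)
    low_ir <- IRanges::IRanges(grid$starts[runs[, "start"]],
                               grid$ends[runs[, "end"]])
    ir <- IRanges::reduce(low_ir, min.gapwidth = params$merge_gap + 1)
    n_low <- IRanges::countOverlaps(
      ir, IRanges::IRanges(grid$starts[low], grid$ends[low]))
    ir <- ir[n_low >= params$hmr_min_bins]
    data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
  })
}

#' Consensus of per-sample hypomethylated regions
#'
#' A consensus HMR is a maximal interval covered by HMRs in at least
#' `min_samples` samples; each candidate must additionally be supported
#' by `min_samples` samples whose own HMR overlaps it reciprocally by at
#' least `min_reciprocal_overlap` of both lengths (guards against a long
#' consensus stitched from barely-overlapping fragments).
#'
#' @param per_sample list of per-sample HMR data.frames (from
#'   [call_hmrs()]).
#' @param min_samples number of samples required (default: all).
#' @param min_reciprocal_overlap reciprocal overlap fraction in (0, 1].
#' @param gene,label_prefix see [call_consensus_segments()].
#' @return a `segment_calls` data.frame (support = fraction of samples
#'   with a reciprocally-overlapping HMR).
#' @export
consistent_hmrs <- function(per_sample, min_samples = length(per_sample),
                            min_reciprocal_overlap = 0.5, gene = NULL,
                            label_prefix = "H") {
  n <- length(per_sample)
  if (n < min_samples) stop("fewer samples than min_samples")
  all_ir <- lapply(per_sample, function(df) IRanges::IRanges(df$start, df$end))
  cov <- IRanges::coverage(do.call(c, unname(all_ir)))
  cand <- IRanges::reduce(IRanges::IRanges(IRanges::slice(cov, lower = min_samples)))
  if (!length(cand)) return(.empty_calls(n))
  keep <- logical(length(cand)); support <- numeric(length(cand))
  for (i in seq_along(cand)) {
    ci <- cand[i]
    ok <- vapply(all_ir, function(ir) {
      if (!length(ir)) return(FALSE)
      ov <- IRanges::width(IRanges::pintersect(
        rep(ci, length(ir)), ir, resolve.empty = "max.start"))
      any(ov / IRanges::width(ci) >= min_reciprocal_overlap &
            ov / IRanges::width(ir) >= min_reciprocal_overlap)
    }, logical(1))
    support[i] <- mean(ok)
    keep[i] <- sum(ok) >= min_samples
  }
  cand <- cand[keep]
  if (!length(cand)) return(.empty_calls(n))
  .label_calls(data.frame(start = IRanges::start(cand),
                          end = IRanges::end(cand),
                          support = support[keep],
                          mean_signal = NA_real_, n_tracks = n),
               gene, label_prefix)
}
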