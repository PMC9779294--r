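region <- c(1, 150000)

test_that("degenerate inputs behave as documented", {
  mk <- function(vals) {
    s <- seq(1, 150000, by = 200)
    signal_track("t", s, pmin(s + 199, 150000), vals)
  }
  zero <- lapply(1:4, function(i) mk(rep(0, 750)))
  expect_equal(nrow(call_consensus_segments(zero, region)), 0L)

  const <- lapply(1:4, function(i) mk(rep(3, 750)))
  calls <- call_consensus_segments(const, region)
  expect_equal(nrow(calls), 1L)
  expect_equal(c(calls$start, calls$end), region)

  expect_error(call_consensus_segments(const, c(5, 4)), "region")
  expect_error(call_consensus_segments(const, c(1, 50)), "bin_size")
  expect_error(call_consensus_segments(list(), region), "track")
})

test_that("planted segments are recovered and labelled in gene order", {
  cfg <- simulation_config(seed = 31)
  locus <- list(locus_length = cfg$locus_length)
  tracks <- simulate_tracks(locus, cfg)
  calls <- call_consensus_segments(tracks, region)
  expect_equal(nrow(calls), 3L)
  expect_gte(union_jaccard(calls, cfg$planted_segments), 0.8)
  expect_equal(calls$label, c("S1", "S2", "S3"))
  expect_true(all(calls$support >= 0 & calls$support <= 1))

  ## a minus-strand gene labels right to left
  gm <- gene_model("g", "chrS", "-", cbind(c(1400, 200), c(1500, 300)),
                   c(sim1 = 1500))
  rev_calls <- call_consensus_segments(tracks, region, gene = gm)
  expect_equal(rev_calls$label[which.max(rev_calls$start)], "S1")
})

test_that("single planted segment at fold 8 gives exactly one accurate call", {
  cfg <- simulation_config(seed = 77, planted_segments = list(
    list(start = 50001, end = 53000, fold = 8, carried = 1)))
  tracks <- simulate_tracks(list(locus_length = 150000), cfg)
  calls <- call_consensus_segments(tracks, region)
  expect_equal(nrow(calls), 1L)
  expect_gte(union_jaccard(calls, cfg$planted_segments), 0.8)
})

test_that("caller output is monotone, order-invariant and idempotent", {
  cfg <- simulation_config(seed = 41, n_tracks = 8)
  tracks <- simulate_tracks(list(locus_length = 150000), cfg)
  base <- call_consensus_segments(tracks, region)

  ## raising the quantile or the consensus fraction never lengthens calls
  for (p2 in list(caller_params(enrich_quantile = 0.95),
                  caller_params(consensus_fraction = 0.9))) {
    stricter <- call_consensus_segments(tracks, region, p2)
    expect_lte(called_length(stricter), called_length(base))
  }

  ## shuffling track order leaves the calls unchanged
  set.seed(1)
  shuffled <- call_consensus_segments(tracks[sample(seq_along(tracks))],
                                      region)
  expect_equal(shuffled, base)

  ## calling on the binary output mask reproduces the segments
  s <- seq(1, 150000, by = 200)
  mask_vals <- as.numeric(vapply(s, function(x)
    any(x >= base$start & x <= base$end), logical(1)))
  mask <- signal_track("mask", s, pmin(s + 199, 150000), mask_vals)
  again <- call_consensus_segments(list(mask), region,
                                   caller_params(consensus_fraction = 1))
  expect_equal(again[, c("start", "end")], base[, c("start", "end")])
})

test_that("HMR calling handles flat tracks and recovers planted regions", {
  s <- seq(1, 150000, by = 200)
  mk <- function(vals, id = "m") methylation_track(id, s,
                                                   pmin(s + 199, 150000),
                                                   vals)
  high <- list(mk(rep(1, 750)))
  expect_equal(nrow(call_hmrs(high, region)[[1]]), 0L)
  low <- list(mk(rep(0, 750)))
  h <- call_hmrs(low, region)[[1]]
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start, h$end), region)
  expect_error(call_hmrs(list(signal_track("x", 1, 200, 2)), region),
               "\\[0, 1\\]")

  cfg <- simulation_config(seed = 55)
  meth <- simulate_methylation(list(locus_length = 150000), cfg)
  per <- call_hmrs(meth, region)
  truth <- lapply(cfg$hmr_regions, function(h) list(start = h[1], end = h[2]))
  for (df in per) expect_gte(union_jaccard(df, truth), 0.8)
})

test_that("consistent HMRs require support across samples", {
  a <- data.frame(start = c(1000, 50000), end = c(3000, 52000))
  same <- list(s1 = a, s2 = a, s3 = a)
  cons <- consistent_hmrs(same)
  expect_equal(cons$start, sort(a$start))
  expect_equal(cons$end, a$end[order(a$start)])
  expect_equal(cons$support, c(1, 1))

  ## a region present in a single sample is excluded at min_samples = 3
  extra <- list(s1 = a, s2 = a,
                s3 = rbind(a, data.frame(start = 90000, end = 91000)))
  cons2 <- consistent_hmrs(extra, min_samples = 3)
  expect_equal(nrow(cons2), 2L)
  expect_error(consistent_hmrs(list(a), min_samples = 2), "fewer samples")

  ## planted HMRs present in every synthetic sample are all recovered
  cfg <- simulation_config(seed = 71)
  meth <- simulate_methylation(list(locus_length = 150000), cfg)
  cons3 <- consistent_hmrs(call_hmrs(meth, region))
  expect_equal(nrow(cons3), length(cfg$hmr_regions))
  truth <- lapply(cfg$hmr_regions, function(h) list(start = h[1], end = h[2]))
  expect_gte(union_jaccard(cons3, truth), 0.8)
})
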