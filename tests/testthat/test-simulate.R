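test_that("configs validate their invariants", {
  expect_error(simulation_config(planted_segments = list(
    list(start = 10, end = 5, fold = 8, carried = 1))), "planted segment")
  expect_error(simulation_config(planted_segments = list(
    list(start = 1, end = 10, fold = 0.5, carried = 1))), "fold")
  expect_error(simulation_config(meth_hmr_beta = c(0, 9)), "Beta")
  expect_error(simulation_config(strand = "x"), "strand")
  ## inconsistent layout: locus shorter than the exon/intron chain
  expect_error(simulate_locus(simulation_config(seed = 2, locus_length = 2000,
                                                planted_segments = list(),
                                                hmr_regions = list())),
               "too small")
})

test_that("locus simulation is deterministic and structurally sound", {
  cfg <- simulation_config(seed = 5, locus_length = 20000,
                           planted_segments = list(), hmr_regions = list())
  a <- simulate_locus(cfg)
  b <- simulate_locus(cfg)
  expect_identical(a$dna, b$dna)
  expect_true(grepl("^[ACGT]+$", a$dna))
  expect_equal(nrow(a$gene$exons), 4L)
  ## minus strand: TSS is the maximum coordinate of exon 1
  expect_equal(a$gene$tss_by_assembly[["sim1"]], max(a$gene$exons[1, ]))
  ## exon peptides translate back from the genomic sequence
  prod <- paste(a$exon_peptides[2:4], collapse = "")
  expect_equal(nchar(prod), sum(nchar(a$exon_peptides[2:4])))

  cfgp <- simulation_config(seed = 5, locus_length = 20000, strand = "+",
                            planted_segments = list(), hmr_regions = list())
  p <- simulate_locus(cfgp)
  expect_equal(p$gene$tss_by_assembly[["sim1"]], min(p$gene$exons[1, ]))
})

test_that("generated truth labels agree with the exon translations", {
  cfg <- simulation_config(seed = 9, locus_length = 20000,
                           planted_segments = list(), hmr_regions = list())
  locus <- simulate_locus(cfg)
  specs <- list(
    list(id = "full", base = "E2"),
    list(id = "e1_style", base = "E1"),
    list(id = "trunc", base = "E2", keep = list(c(40, 200))))
  isos <- simulate_isoforms(locus, specs)
  for (id in names(isos)) {
    pr <- exon_provenance(stats::setNames(isos[[id]]$sequence, id),
                          locus$exon_peptides)
    expect_equal(pr$labels, isos[[id]]$truth_labels, info = id)
  }
  ## two N-terminal variants differ only at the N terminus
  td <- terminal_diff(isos[["e1_style"]]$sequence, isos[["full"]]$sequence)
  expect_equal(td$terminus, "N")
  expect_equal(td$a, 21L)
  expect_equal(td$b, 9L)
  expect_error(simulate_isoforms(locus, list(list(id = "bad", base = "E2",
                                                  keep = list(c(2, 1))))),
               "keep range")
})

test_that("planted track enrichment matches the Poisson expectation", {
  cfg <- simulation_config(seed = 21)
  locus <- list(locus_length = cfg$locus_length)
  tracks <- simulate_tracks(locus, cfg)
  expect_length(tracks, cfg$n_tracks)
  ## identical on regeneration, including the written bedGraph
  tracks2 <- simulate_tracks(locus, cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_bedgraph(tracks[[1]], f1); write_bedgraph(tracks2[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))

  seg <- cfg$planted_segments[[3]]           # 5 kb = 25 bins per track
  vals_in <- unlist(lapply(tracks, function(tr)
    tr$value[tr$start >= seg$start & tr$end <= seg$end]))
  vals_out <- unlist(lapply(tracks, function(tr)
    tr$value[tr$start > 130000]))
  expect_gt(length(vals_in), 50)
  expect_equal(mean(vals_in), seg$fold * cfg$background_rate,
               tolerance = 0.05)
  expect_equal(mean(vals_out), cfg$background_rate, tolerance = 0.05)
})

test_that("methylation fractions follow the configured Beta mixtures", {
  cfg <- simulation_config(seed = 13)
  locus <- list(locus_length = cfg$locus_length)
  meth <- simulate_methylation(locus, cfg)
  expect_length(meth, cfg$n_samples)
  all_fr <- unlist(lapply(meth, `[[`, "value"))
  expect_true(all(all_fr >= 0 & all_fr <= 1))
  in_hmr <- function(tr) {
    sel <- rep(FALSE, nrow(tr))
    for (h in cfg$hmr_regions) sel <- sel | (tr$start >= h[1] & tr$end <= h[2])
    sel
  }
  fr_in <- unlist(lapply(meth, function(tr) tr$value[in_hmr(tr)]))
  fr_out <- unlist(lapply(meth, function(tr) tr$value[!in_hmr(tr)]))
  expect_equal(mean(fr_in), 1 / (1 + 9), tolerance = 0.1)   # Beta(1,9)
  expect_equal(mean(fr_out), 8 / (8 + 2), tolerance = 0.02) # Beta(8,2)

  ## no HMRs configured: no bin is systematically low
  cfg0 <- simulation_config(seed = 13, hmr_regions = list())
  m0 <- simulate_methylation(locus, cfg0, n_samples = 4)
  low_by_bin <- Reduce(`+`, lapply(m0, function(tr) tr$value <= 0.3))
  expect_lte(max(low_by_bin), 1)  # chance lows, never consistent ones
})
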