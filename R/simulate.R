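#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators. The defaults
#' emulate the statistical character of the study conditions the package
#' targets: a ~150 kb locus viewed in 200-bp bins, seven signal tracks
#' (one per brain region in a typical histone-PTM panel), six methylation
#' samples (one per donor age), kb-scale planted segments at 8-fold
#' enrichment carried by every track, and methylation fractions drawn from
#' Beta(8,2) background (mean 0.8) versus Beta(1,9) inside hypomethylated
#' regions (mean 0.1).
#'
#' @param seed integer seed; a fixed seed makes every generator
#'   byte-identical on rerun.
#' @param locus_length locus size in bases.
#' @param n_exons number of exons for the simulated gene.
#' @param strand gene strand.
#' @param n_tracks number of signal tracks.
#' @param planted_segments list of `list(start, end, fold, carried)`:
#'   interval, enrichment fold (> 1 to plant, 1 for the null), and the
#'   fraction of tracks carrying the segment.
#' @param background_rate mean Poisson signal per bin outside segments.
#' @param bin_size bin width in bases.
#' @param hmr_regions list of `c(start, end)` hypomethylated intervals.
#' @param meth_background_beta,meth_hmr_beta `c(alpha, beta)` Beta
#'   parameters (both positive) for background and in-HMR fractions.
#' @param n_samples number of methylation samples.
#' @param variant_specs list of declarative splice-variant edits for
#'   [simulate_isoforms()].
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              locus_length = 150000,
                              n_exons = 4L,
                              strand = "-",
                              n_tracks = 7L,
                              planted_segments = list(
                                list(start = 20001, end = 23000, fold = 8,
                                     carried = 1),
                                list(start = 60001, end = 62000, fold = 8,
                                     carried = 1),
                                list(start = 110001, end = 115000, fold = 8,
                                     carried = 1)),
                              background_rate = 5,
                              bin_size = 200,
                              hmr_regions = list(c(30001, 32000),
                                                 c(80001, 81500),
                                                 c(120001, 124000)),
                              meth_background_beta = c(8, 2),
                              meth_hmr_beta = c(1, 9),
                              n_samples = 6L,
                              variant_specs = list()) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (n_exons < 2L) stop("need at least 2 exons")
  if (n_tracks < 1L) stop("need at least 1 track")
  for (ps in planted_segments) {
    if (ps$fold < 1) stop("enrichment fold must be >= 1")
    if (ps$start < 1 || ps$end > locus_length || ps$start > ps$end)
      stop("planted segment outside the locus")
    if (ps$carried < 0 || ps$carried > 1)
      stop("carried fraction must lie in [0, 1]")
  }
  for (h in hmr_regions)
    if (h[1] < 1 || h[2] > locus_length || h[1] > h[2])
      stop("HMR region outside the locus")
  if (any(c(meth_background_beta, meth_hmr_beta) <= 0))
    stop("Beta parameters must be positive")
  structure(list(seed = as.integer(seed), locus_length = locus_length,
                 n_exons = as.integer(n_exons), strand = strand,
                 n_tracks = as.integer(n_tracks),
                 planted_segments = planted_segments,
                 background_rate = background_rate, bin_size = bin_size,
                 hmr_regions = hmr_regions,
                 meth_background_beta = meth_background_beta,
                 meth_hmr_beta = meth_hmr_beta,
                 n_samples = as.integer(n_samples),
                 variant_specs = variant_specs),
            class = "simulation_config")
}

## run code with a locally-seeded RNG, restoring global RNG state after
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

.AA20 <- strsplit("ACDEFGHIKLNPQRSTVWY", "")[[1L]]  # no M: starts stay unique

.random_peptide <- function(n, force_met_at = integer(0)) {
  p <- sample(.AA20, n, replace = TRUE)
  p[force_met_at] <- "M"
  paste(p, collapse = "")
}

## inverse genetic code: AA -> codons (stops excluded)
.codons_for <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

.back_translate <- function(pep) {
  tab <- .codons_for()
  aa <- strsplit(pep, "")[[1L]]
  paste(vapply(aa, function(a) {
    cods <- tab[[a]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

.revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Simulate a multi-exon gene locus
#'
#' Builds a locus with `n_exons` exons whose coding parts are
#' back-translated from randomly generated exon peptides, so the exon
#' phases are consistent and exons 3..n are translatable in one frame.
#' Exons 1 and 2 both begin with a start codon (alternative translation
#' starts, the topology of a four-exon gene with two N-terminal splice
#' isoforms). On the minus strand the returned DNA is the plus-strand
#' genomic sequence and the TSS is the maximum coordinate of exon 1.
#'
#' @param config a [simulation_config].
#' @return object of class `sim_locus`: list with `gene` (a
#'   [gene_model]), `dna` (plus-strand locus sequence), `exon_peptides`
#'   (translated coding part of each exon, transcription order) and
#'   layout details used by [simulate_isoforms()].
#' @export
simulate_locus <- function(config) {
  .with_seed(config$seed, {
    n <- config$n_exons
    pep_len <- c(21L, 9L, sample(60L:140L, max(0L, n - 2L), replace = TRUE))
    peps <- character(n)
    peps[1L] <- .random_peptide(pep_len[1L], force_met_at = 1L)
    if (n >= 2L) peps[2L] <- .random_peptide(pep_len[2L], force_met_at = 1L)
    if (n >= 3L) for (k in 3L:n) peps[k] <- .random_peptide(pep_len[k])
    .assemble_locus(config, peps,
                    utr5 = c(sample(80L:200L, 1L), sample(10L:40L, 1L)),
                    utr3 = sample(150L:400L, 1L),
                    introns = sample(300L:800L, n - 1L, replace = TRUE),
                    flank5 = 500L)
  })
}

## shared locus assembly (expects RNG already seeded)
.assemble_locus <- function(config, peps, utr5, utr3, introns, flank5) {
  n <- length(peps)
  cds <- vapply(peps, .back_translate, character(1))
  exon_seq <- character(n)
  exon_seq[1L] <- paste0(.random_dna(utr5[1L]), cds[1L])
  if (n >= 2L)
    exon_seq[2L] <- paste0(.random_dna(utr5[2L]), cds[2L])
  if (n >= 3L) for (k in 3L:(n - 1L)) exon_seq[k] <- cds[k]
  exon_seq[n] <- paste0(cds[n], "TAA", .random_dna(utr3))
  intron_seq <- vapply(introns, .random_dna, character(1))

  parts <- character(0)
  for (k in seq_len(n)) {
    parts <- c(parts, exon_seq[k])
    if (k < n) parts <- c(parts, intron_seq[k])
  }
  body <- paste(parts, collapse = "")
  used <- flank5 + nchar(body)
  if (config$locus_length < used + 1L)
    stop("locus_length ", config$locus_length,
         " too small for the exon layout (needs > ", used, ")")
  sense <- paste0(.random_dna(flank5), body,
                  .random_dna(config$locus_length - used))

  ## transcript-direction (sense) exon coordinates
  starts <- integer(n); ends <- integer(n)
  pos <- flank5 + 1L
  for (k in seq_len(n)) {
    starts[k] <- pos
    ends[k] <- pos + nchar(exon_seq[k]) - 1L
    pos <- ends[k] + 1L
    if (k < n) pos <- pos + nchar(intron_seq[k])
  }
  ## coding sub-interval of each exon in sense coordinates
  cds_start <- starts
  cds_start[1L] <- starts[1L] + utr5[1L]
  if (n >= 2L) cds_start[2L] <- starts[2L] + utr5[2L]
  cds_end <- cds_start + nchar(cds) - 1L

  L <- config$locus_length
  if (config$strand == "-") {
    dna <- .revcomp(sense)
    g <- function(t) L - t + 1
    exons <- cbind(start = g(ends), end = g(starts))
    cds_g <- cbind(start = g(cds_end), end = g(cds_start))
  } else {
    dna <- sense
    exons <- cbind(start = starts, end = ends)
    cds_g <- cbind(start = cds_start, end = cds_end)
  }
  tss <- if (config$strand == "-") max(exons[1L, ]) else min(exons[1L, ])
  gene <- gene_model("simgene", "chrS", config$strand, exons,
                     tss_by_assembly = c(sim1 = tss), cds = cds_g)
  structure(list(gene = gene, dna = dna, exon_peptides = unname(peps),
                 sense = sense,
                 sense_exons = cbind(start = starts, end = ends),
                 sense_cds = cbind(start = cds_start, end = cds_end),
                 locus_length = L),
            class = "sim_locus")
}

## sense-direction sequence of an exon/intron feature
.feature_sense_seq <- function(locus, feature, index) {
  se <- locus$sense_exons
  if (feature == "exon") {
    s <- se[index, "start"]; e <- se[index, "end"]
  } else {
    s <- se[index, "end"] + 1L; e <- se[index + 1L, "start"] - 1L
  }
  substr(locus$sense, s, e)
}

## first stop-free window of length_aa starting at frame_offset (nt) in a
## sense-direction feature sequence; returns the peptide and nt offset
.stop_free_window <- function(seqs, frame_offset, length_aa,
                              search_from = 1L) {
  need <- 3L * length_aa
  prot <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(seqs, frame_offset + 1L,
                                 frame_offset + (nchar(seqs) - frame_offset) %/% 3L * 3L)),
    if.fuzzy.codon = "X")))
  aa <- strsplit(prot, "")[[1L]]
  ok <- aa != "*"
  for (w in search_from:(length(aa) - length_aa + 1L)) {
    if (all(ok[w:(w + length_aa - 1L)]))
      return(list(peptide = paste(aa[w:(w + length_aa - 1L)], collapse = ""),
                  aa_offset = w,
                  nt_offset = frame_offset + 3L * (w - 1L)))
  }
  stop("no stop-free window of ", length_aa, " aa found")
}

#' Simulate splice-variant protein isoforms with known truth
#'
#' Applies declarative edit specifications to the simulated locus and
#' returns isoform sequences together with ground-truth labels (the kept
#' reference positions, per-residue exon of origin, and the origin of any
#' novel fragment), so provenance labelling and domain classification can
#' be validated against construction.
#'
#' Each spec is a list with an `id` and:
#' \describe{
#'   \item{`base`}{`"E2"` (translation starts in exon 2; the reference
#'     product) or `"E1"` (exon 2 skipped, translation starts in exon 1).}
#'   \item{`keep`}{optional list of `c(start, end)` residue ranges of the
#'     base product to keep, concatenated in order (default: the full
#'     product). Dropping a prefix emulates a truncated N-terminus
#'     starting at an internal residue; dropping interior ranges emulates
#'     fragmentary products.}
#'   \item{`novel`}{optional alternative C-terminus:
#'     `list(feature, index, frame_offset, length_aa, search_from)` takes
#'     the first stop-free window of the named intron/exon translated at
#'     `frame_offset` (sense direction), or `peptide = "..."` supplies the
#'     fragment directly.}
#' }
#'
#' @param locus a `sim_locus`.
#' @param specs list of edit specifications (defaults to
#'   `config$variant_specs` stored in the locus call).
#' @return named list of class `sim_isoforms`: per isoform a list with
#'   `sequence`, `base`, `kept_ref` (ranges in base-product coordinates),
#'   `truth_labels` (per-residue `"exon<k>"`/`"novel"`), `novel_origin`.
#' @export
simulate_isoforms <- function(locus, specs) {
  n <- length(locus$exon_peptides)
  peps <- locus$exon_peptides
  products <- list(
    E2 = list(seq = paste(peps[2:n], collapse = ""),
              exon_of = rep(2:n, nchar(peps[2:n]))),
    E1 = list(seq = paste(peps[c(1L, 3:n)], collapse = ""),
              exon_of = rep(c(1L, 3:n), nchar(peps[c(1L, 3:n)])))
  )
  out <- list()
  for (sp in specs) {
    base <- sp$base %||% "E2"
    prod <- products[[base]]
    if (is.null(prod)) stop("unknown base product '", base, "'")
    keep <- sp$keep %||% list(c(1L, nchar(prod$seq)))
    res <- character(0); labels <- character(0); kept <- list()
    for (rg in keep) {
      if (rg[1] < 1 || rg[2] > nchar(prod$seq) || rg[1] > rg[2])
        stop("spec '", sp$id, "': keep range outside the base product")
      idx <- rg[1]:rg[2]
      res <- c(res, strsplit(substr(prod$seq, rg[1], rg[2]), "")[[1L]])
      labels <- c(labels, paste0("exon", prod$exon_of[idx]))
      kept[[length(kept) + 1L]] <- c(rg[1], rg[2])
    }
    novel_origin <- NULL
    if (!is.null(sp$novel)) {
      nv <- sp$novel
      if (!is.null(nv$peptide)) {
        pep <- nv$peptide
        novel_origin <- list(feature = nv$feature %||% NA_character_,
                             index = nv$index %||% NA_integer_)
      } else {
        fs <- .feature_sense_seq(locus, nv$feature, nv$index)
        win <- .stop_free_window(fs, nv$frame_offset %||% 0L, nv$length_aa,
                                 nv$search_from %||% 1L)
        pep <- win$peptide
        novel_origin <- list(feature = nv$feature, index = nv$index,
                             frame_offset = nv$frame_offset %||% 0L,
                             nt_offset = win$nt_offset)
      }
      res <- c(res, strsplit(pep, "")[[1L]])
      labels <- c(labels, rep("novel", nchar(pep)))
    }
    if (!length(res))
      stop("spec '", sp$id, "' produces an empty protein")
    out[[sp$id]] <- list(sequence = paste(res, collapse = ""), base = base,
                         kept_ref = kept, truth_labels = labels,
                         novel_origin = novel_origin)
  }
  class(out) <- "sim_isoforms"
  out
}

#' Simulate multi-sample signal tracks with planted enrichment
#'
#' Per-bin values are Poisson with the background rate, multiplied by the
#' enrichment fold inside each planted segment for the (seeded, random)
#' subset of tracks carrying it. The bin size is recorded on each track.
#'
#' @param locus a `sim_locus` (or any list with `locus_length`).
#' @param config a [simulation_config].
#' @return list of [signal_track]s with a `truth` attribute (the planted
#'   segments and carrying tracks).
#' @export
simulate_tracks <- function(locus, config) {
  .with_seed(config$seed + 1L, {
    L <- locus$locus_length %||% config$locus_length
    bs <- config$bin_size
    starts <- seq(1, L, by = bs)
    ends <- pmin(starts + bs - 1, L)
    nb <- length(starts)
    carriers <- lapply(config$planted_segments, function(ps) {
      k <- round(ps$carried * config$n_tracks)
      if (k > 0L) sort(sample.int(config$n_tracks, k)) else integer(0)
    })
    tracks <- vector("list", config$n_tracks)
    for (t in seq_len(config$n_tracks)) {
      lambda <- rep(config$background_rate, nb)
      for (si in seq_along(config$planted_segments)) {
        ps <- config$planted_segments[[si]]
        if (t %in% carriers[[si]]) {
          inside <- starts <= ps$end & ends >= ps$start
          lambda[inside] <- lambda[inside] * ps$fold
        }
      }
      vals <- stats::rpois(nb, lambda)
      tr <- signal_track(paste0("track", t), starts, ends, vals,
                         chromosome = "chrS", assay = "ChIP")
      attr(tr, "bin_size") <- bs
      tracks[[t]] <- tr
    }
    attr(tracks, "truth") <- list(segments = config$planted_segments,
                                  carriers = carriers)
    tracks
  })
}

#' Simulate multi-sample methylation tracks with planted HMRs
#'
#' Per-bin methylation fractions are drawn independently per sample from
#' `Beta(meth_background_beta)` outside the configured hypomethylated
#' regions and `Beta(meth_hmr_beta)` inside them.
#'
#' @param locus a `sim_locus` (or any list with `locus_length`).
#' @param config a [simulation_config].
#' @param n_samples number of samples (default from the config).
#' @return list of [methylation_track]s with a `truth` attribute.
#' @export
simulate_methylation <- function(locus, config, n_samples = config$n_samples) {
  .with_seed(config$seed + 2L, {
    L <- locus$locus_length %||% config$locus_length
    bs <- config$bin_size
    starts <- seq(1, L, by = bs)
    ends <- pmin(starts + bs - 1, L)
    nb <- length(starts)
    in_hmr <- rep(FALSE, nb)
    for (h in config$hmr_regions)
      in_hmr <- in_hmr | (starts <= h[2] & ends >= h[1])
    bg <- config$meth_background_beta
    hm <- config$meth_hmr_beta
    lapply(seq_len(n_samples), function(s) {
      fr <- numeric(nb)
      fr[!in_hmr] <- stats::rbeta(sum(!in_hmr), bg[1], bg[2])
      fr[in_hmr] <- stats::rbeta(sum(in_hmr), hm[1], hm[2])
      tr <- methylation_track(paste0("sample", s), starts, ends, fr,
                              chromosome = "chrS",
                              age_label = paste0("age", s))
      attr(tr, "bin_size") <- bs
      attr(tr, "truth") <- config$hmr_regions
      tr
    })
  })
}
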