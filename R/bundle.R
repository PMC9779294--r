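#' Deterministic synthetic reference bundle for the MECP2-like locus
#'
#' Builds, from a fixed internal seed, a complete synthetic stand-in for
#' the reference objects the isoform analysis needs: a minus-strand
#' four-exon locus, the two established splice isoforms (E1-style and
#' E2-style, which differ only in their N-termini: the canonical
#' 21-residue MAAAAAAAPSGGGGGGEEERL versus the 9-residue MVAGMLGLR), the
#' database-style predicted isoforms whose exon/fragment architecture
#' follows the published record descriptions (truncated N- or C-termini,
#' fragmentary exon-4 products, alternative C-termini translated from
#' intron 2 or from exon 4 in a shifted frame), and a functional-domain
#' annotation anchored on the E2-style reference.
#'
#' The sequences are synthetic: only the two N-termini and the gene
#' topology are the canonical published ones; all downstream residues and
#' the domain coordinates are generated placements chosen to be mutually
#' consistent with the documented isoform architecture. The packaged
#' `inst/extdata/synthetic_*` fixtures are this bundle's serialized form.
#'
#' @return list with `locus` (a `sim_locus`), `isoforms`
#'   (a `sim_isoforms` truth set), `sequences` (named character vector),
#'   `references` (named vector: `isoform1` = E2-style, `isoform2` =
#'   E1-style), `domains` (a `functional_domains` table) and
#'   `exon_peptides`.
#' @export
synthetic_mecp2_bundle <- function() {
  seed <- 20221015L
  locus <- .with_seed(seed, {
    pep1 <- "MAAAAAAAPSGGGGGGEEERL"         # E1-style N-terminus (21 aa)
    pep2 <- "MVAGMLGLR"                     # E2-style N-terminus (9 aa)
    pep3 <- paste0("EEKSEDQ",
                   .random_peptide(99, force_met_at = 74L))  # pos 81 = M
    pep4 <- .random_peptide(371, force_met_at = 95L)         # E2 pos 210 = M
    cfg <- simulation_config(seed = seed, locus_length = 20000,
                             n_exons = 4L, strand = "-",
                             planted_segments = list(),
                             hmr_regions = list())
    .assemble_locus(cfg, c(pep1, pep2, pep3, pep4),
                    utr5 = c(120L, 15L), utr3 = 300L,
                    introns = c(800L, 600L, 700L), flank5 = 500L)
  })

  ## alternative C-terminal fragments with the documented relationships:
  ## one exon-4 fragment in a shifted frame shared by two isoforms, and
  ## intron-2 fragments of which two share exactly their last 14 residues
  bwin <- .stop_free_window(.feature_sense_seq(locus, "exon", 4L), 1L, 40L)
  novelB <- bwin$peptide
  int2 <- .feature_sense_seq(locus, "intron", 2L)
  from <- 1L
  repeat {
    fwin <- .stop_free_window(int2, 0L, 20L, search_from = from)
    if (substr(fwin$peptide, 6L, 6L) != "L") break  # keep the shared
    from <- fwin$aa_offset + 1L                     # suffix exactly 14
  }
  novelF <- fwin$peptide
  novelH <- substr(novelF, 7L, 20L)
  pwin <- .stop_free_window(int2, 0L, 20L, search_from = fwin$aa_offset + 20L)
  novelP <- pwin$peptide

  specs <- list(
    list(id = "isoform1", base = "E2"),
    list(id = "isoform2", base = "E1"),
    list(id = "isoform3", base = "E2", keep = list(c(90, 486))),
    list(id = "isoform4", base = "E2", keep = list(c(210, 486))),
    list(id = "B5MCB4", base = "E1", keep = list(c(1, 170)),
         novel = list(peptide = novelB, feature = "exon", index = 4L)),
    list(id = "A0A0D9SFX7", base = "E2", keep = list(c(1, 161)),
         novel = list(peptide = novelB, feature = "exon", index = 4L)),
    list(id = "C9JH89", base = "E2", keep = list(c(1, 40))),
    list(id = "A0A1B0GTV0", base = "E2", keep = list(c(116, 130),
                                                     c(240, 320))),
    list(id = "A0A0D9SEX1", base = "E2", keep = list(c(1, 45))),
    list(id = "H7BY72", base = "E2", keep = list(c(1, 8)),
         novel = list(peptide = novelH, feature = "intron", index = 2L)),
    list(id = "A0A6Q8PHQ3", base = "E2", keep = list(c(1, 9)),
         novel = list(peptide = novelP, feature = "intron", index = 2L)),
    list(id = "A0A6Q8PF93", base = "E2", keep = list(c(1, 9)),
         novel = list(peptide = novelF, feature = "intron", index = 2L))
  )
  isoforms <- simulate_isoforms(locus, specs)
  sequences <- vapply(isoforms, `[[`, character(1), "sequence")

  domains <- data.frame(
    name = c("HMGD1", "MBD", "H3-M-T IS", "HMGD2", "aDBD", "NLS1",
             "AT-hook 1", "TRD", "NID", "TBL1XR1 IS", "NLS2", "AT-hook 2",
             "WW-2 IS", "CTDalpha", "CTDbeta"),
    ref_isoform = "isoform1",
    start = c(1,  78,  85, 157, 168, 173, 184, 207, 225, 228, 330, 350,
              365, 300, 425),
    end   = c(55, 165, 115, 190, 252, 193, 195, 310, 262, 258, 346, 361,
              375, 420, 486),
    source = "synthetic placement",
    stringsAsFactors = FALSE)
  class(domains) <- c("functional_domains", "data.frame")

  list(locus = locus, isoforms = isoforms, sequences = sequences,
       references = c(isoform1 = unname(sequences[["isoform1"]]),
                      isoform2 = unname(sequences[["isoform2"]])),
       domains = domains, exon_peptides = locus$exon_peptides)
}

#' Expected domain status of a constructed isoform
#'
#' Computes, from a `sim_isoforms` truth record (the kept base-product
#' ranges), the domain status a classifier should report: the kept ranges
#' are mapped into the reference product's coordinates and compared with
#' the domain interval. Used to validate [classify_domain()] against
#' construction rather than against another alignment.
#'
#' @param iso one element of a `sim_isoforms` list.
#' @param domain one row of a `functional_domains` table (coordinates on
#'   the E2-style reference product).
#' @param n_term_exon1 number of residues an E1-style base contributes
#'   before the shared part (default 21) and `n_term_exon2` its E2-style
#'   counterpart (default 9), used to map E1 coordinates onto E2.
#' @param missing_threshold as in [classify_domain()].
#' @return a `domain_status`.
#' @export
truth_domain_status <- function(iso, domain, n_term_exon1 = 21L,
                                n_term_exon2 = 9L, missing_threshold = 0.1) {
  kept_e2 <- integer(0)
  alt_prefix <- FALSE
  for (rg in iso$kept_ref) {
    idx <- rg[1]:rg[2]
    if (iso$base == "E2") kept_e2 <- c(kept_e2, idx)
    else {
      ## E1 positions <= n_term_exon1 are the alternative N-terminus
      alt_prefix <- alt_prefix || any(idx <= n_term_exon1)
      shared <- idx[idx > n_term_exon1]
      kept_e2 <- c(kept_e2, shared - n_term_exon1 + n_term_exon2)
    }
  }
  dom <- domain$start:domain$end
  m_local <- which(dom %in% kept_e2)
  st <- .status_from_matched(m_local, length(dom), missing_threshold,
                             offset = domain$start - 1L)
  if (st$category == "n_incomplete" && alt_prefix &&
      all(setdiff(dom, dom[m_local]) <= n_term_exon2))
    st$category <- "alternative_n_terminus"
  st
}
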