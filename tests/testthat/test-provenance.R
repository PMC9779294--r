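bundle <- synthetic_mecp2_bundle()

test_that("exon provenance labels constructed isoforms exactly", {
  peps <- bundle$exon_peptides
  ## E2-style product = exons 2..4 concatenated: no novel residues
  e2 <- bundle$sequences[["isoform1"]]
  pr <- exon_provenance(c(isoform1 = e2), peps)
  expect_equal(nrow(pr$novel_segments), 0L)
  expect_equal(pr$labels[1:9], rep("exon2", 9))
  expect_false(any(pr$labels == "exon1"))

  ## E1-style isoform: N-terminal run from exon 1, no exon-2 labels
  e1 <- bundle$sequences[["isoform2"]]
  pr1 <- exon_provenance(c(isoform2 = e1), peps)
  expect_equal(pr1$labels[1:21], rep("exon1", 21))
  expect_false(any(pr1$labels == "exon2"))

  ## intron-derived C-terminus becomes one novel segment at the end
  h7 <- bundle$sequences[["H7BY72"]]
  pr7 <- exon_provenance(c(H7BY72 = h7), peps)
  expect_equal(nrow(pr7$novel_segments), 1L)
  expect_equal(unname(pr7$novel_segments[1, "end"]), nchar(h7))
  expect_equal(unname(pr7$novel_segments[1, "start"]), 9L)
})

test_that("provenance truth labels from the generator are recovered", {
  peps <- bundle$exon_peptides
  for (id in names(bundle$isoforms)) {
    iso <- bundle$isoforms[[id]]
    pr <- exon_provenance(stats::setNames(iso$sequence, id), peps)
    expect_equal(pr$labels, iso$truth_labels, info = id)
  }
})

test_that("provenance is stable under a FASTA round trip", {
  tmp <- tempfile(fileext = ".fa")
  write_fasta(bundle$sequences, tmp)
  back <- read_protein_fasta(tmp)
  expect_identical(unname(back), unname(bundle$sequences))
  pr <- exon_provenance(back["B5MCB4"], bundle$exon_peptides)
  expect_equal(pr$labels, bundle$isoforms[["B5MCB4"]]$truth_labels)
})

test_that("terminal differences follow the longest common terminus", {
  expect_equal(terminal_diff("WWAC", "YAC"),
               list(a = 2L, b = 1L, terminus = "N"))
  expect_equal(terminal_diff("MVAG", "MVAG"),
               list(a = 0L, b = 0L, terminus = "N"))
  ## symmetry: swapping inputs swaps the counts
  td <- terminal_diff(bundle$sequences[["isoform2"]],
                      bundle$sequences[["isoform1"]])
  ts <- terminal_diff(bundle$sequences[["isoform1"]],
                      bundle$sequences[["isoform2"]])
  expect_equal(td$a, ts$b)
  expect_equal(td$b, ts$a)
  expect_equal(td$terminus, "N")
  expect_error(terminal_diff("AAA", "CCC"), "common terminus")
})

test_that("shared terminal fragments count common prefixes/suffixes", {
  expect_equal(shared_terminal_fragment("MVA", "MVC", "N"), 2L)
  expect_equal(shared_terminal_fragment("WAC", "YYY", "C"), 0L)
  expect_equal(shared_terminal_fragment("MVAG", "MVAG", "C"), 4L)
})

test_that("novel fragments are located in the correct locus feature", {
  locus <- bundle$locus
  gene <- locus$gene
  dna <- locus$dna

  ## intron-2 fragment planted by the generator: exact hit in intron 2
  pf93 <- bundle$isoforms[["A0A6Q8PF93"]]
  novel <- substr(pf93$sequence, 10, nchar(pf93$sequence))
  hit <- locate_novel_fragment(novel, gene, dna)
  expect_equal(hit$locus_feature, "intron")
  expect_equal(hit$feature_index, 2L)
  expect_equal(hit$match_identity, 1.0)

  ## shifted-frame exon-4 fragment maps back to exon 4
  b5 <- bundle$isoforms[["B5MCB4"]]
  novelB <- substr(b5$sequence, 171, nchar(b5$sequence))
  hitB <- locate_novel_fragment(novelB, gene, dna)
  expect_equal(hitB$locus_feature, "exon")
  expect_equal(hitB$feature_index, 4L)
  expect_equal(hitB$match_identity, 1.0)

  ## a random peptide does not reach the identity threshold
  set.seed(5)
  rnd <- random_aa(25)
  miss <- locate_novel_fragment(rnd, gene, dna, min_identity = 0.9)
  expect_equal(miss$locus_feature, "none")
  expect_lt(miss$match_identity, 0.9)
  expect_error(locate_novel_fragment("MVA", gene, dna), "at least 6")
})

test_that("FASTA reading handles case, line endings and bad records", {
  tmp_lf <- tempfile(); tmp_crlf <- tempfile()
  writeLines(c(">a desc", "mvag", ">b", "ACDE"), tmp_lf, sep = "\n")
  writeLines(c(">a desc", "mvag", ">b", "ACDE"), tmp_crlf, sep = "\r\n")
  lf <- read_protein_fasta(tmp_lf)
  expect_identical(read_protein_fasta(tmp_crlf), lf)
  expect_equal(names(lf), c("a", "b"))
  expect_equal(unname(lf["a"]), "MVAG")

  dup <- tempfile()
  writeLines(c(">a", "MVAG", ">a", "ACDE"), dup)
  expect_error(read_protein_fasta(dup), "duplicate")
  empty <- tempfile()
  writeLines(c(">a", "", ">b", "ACDE"), empty)
  expect_error(read_protein_fasta(empty), "empty")
})
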