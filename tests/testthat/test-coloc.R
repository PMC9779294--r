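segs <- utils::read.delim(ext_fixture("segments_relative.tsv"),
                          comment.char = "#")
set_of <- function(code) {
  d <- segs[segs$set == code, ]
  as_fragment_set(relative_intervals(d$label, d$start_kb, d$end_kb,
                                     assembly = d$assembly[1]), code)
}

test_that("overlap matrices have the exact symmetry and bound properties", {
  H <- set_of("H")
  om <- overlap_matrix(H, H)
  expect_equal(unname(diag(om$jaccard)), rep(1, nrow(H)))
  expect_true(all(om$jaccard >= 0 & om$jaccard <= 1))
  ## symmetry under argument swap = transposition
  A <- set_of("A")
  ab <- overlap_matrix(A, H)
  ba <- overlap_matrix(H, A)
  expect_equal(ab$jaccard, t(ba$jaccard))
  expect_equal(ab$overlap, t(ba$overlap))

  disjoint <- fragment_set("X", c("x1", "x2"), c(0, 100), c(50, 150),
                           space = "relative")
  far <- fragment_set("Y", "y1", 1000, 2000, space = "relative")
  expect_true(all(overlap_matrix(disjoint, far)$overlap == 0))
})

test_that("printed fragment coordinates reproduce the reported relations", {
  A <- set_of("A"); H <- set_of("H")
  om <- overlap_matrix(A, H)
  ## A4 (50.9-51.3 kb) is fully contained in H3 (50.2-51.5 kb): 0.4 kb
  expect_equal(om$overlap["A4", "H3"], 400)
  rep <- containment_report(H, A)
  expect_equal(rep$relation[rep$fragment == "H3" & rep$feature == "A4"],
               "contained")
  ## containment implies Jaccard = |small| / |large|
  expect_equal(om$jaccard["A4", "H3"], 400 / 1300)
})

test_that("overlap operations agree with the quadratic-scan oracle", {
  set.seed(8)
  for (i in 1:20) {
    a <- random_fragment_set("a", sample(5:40, 1))
    b <- random_fragment_set("b", sample(5:40, 1))
    om <- overlap_matrix(a, b)
    bf <- bf_overlap_matrix(a, b)
    expect_equal(unname(om$overlap), bf$overlap)
    expect_equal(unname(om$jaccard), bf$jaccard)

    ## containment report against the same scan
    rep <- containment_report(a, b, keep_none = TRUE)
    for (r in sample(nrow(rep), 10)) {
      i_a <- which(a$label == rep$fragment[r])
      i_b <- which(b$label == rep$feature[r])
      expect_equal(rep$overlap[r], bf$overlap[i_a, i_b])
      want <- if (bf$overlap[i_a, i_b] == 0) "none"
      else if (b$start[i_b] >= a$start[i_a] && b$end[i_b] <= a$end[i_a])
        "contained" else "partial"
      expect_equal(rep$relation[r], want)
    }
  }
})

test_that("set intersection respects the minimum overlap and identities", {
  A <- set_of("A"); H <- set_of("H")
  self <- intersect_sets(A, A)
  expect_equal(nrow(self), nrow(A))
  expect_equal(self$end - self$start, A$end - A$start)

  empty <- fragment_set("E", character(0), numeric(0), numeric(0),
                        space = "relative")
  expect_equal(nrow(intersect_sets(A, empty)), 0L)

  ## the reported co-localization: most accessibility fragments overlap a
  ## hypomethylated fragment (count computed, not assumed)
  ah <- intersect_sets(A, H)
  bf <- bf_overlap_matrix(A, H)
  expect_equal(nrow(ah), sum(bf$overlap >= 1))
  frac_a_hit <- mean(rowSums(bf$overlap >= 1) > 0)
  expect_gt(frac_a_hit, 0.5)
})

test_that("mixed coordinate spaces require and use a gene anchor", {
  H <- set_of("H")
  gm <- mecp2_gene_model()
  genomic_H <- fragment_set("Hg", H$label,
                            153363188 - H$end + 1, 153363188 - H$start + 1,
                            space = "genomic")
  expect_error(overlap_matrix(H, genomic_H), "coordinate spaces")
  om <- overlap_matrix(H, genomic_H, gene = gm)
  expect_equal(unname(diag(om$jaccard)), rep(1, nrow(H)))

  ## the fixture cis-REs land where the prose places them: F3 inside H2
  cr <- utils::read.delim(ext_fixture("cisre_fixture.tsv"),
                          comment.char = "#")
  FR <- as_fragment_set(relative_intervals(cr$label, cr$start_kb,
                                           cr$end_kb), "F")
  rep <- containment_report(H, FR)
  expect_equal(rep$relation[rep$fragment == "H2" & rep$feature == "F3"],
               "contained")
  h1 <- rep[rep$fragment == "H1", ]
  expect_true(all(c("core promoter", "universal enhancer",
                    "silencer of astrocytoma") %in%
                    h1$feature[h1$relation == "contained"]))
})
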