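bundle <- synthetic_mecp2_bundle()
ref <- c(isoform1 = unname(bundle$sequences[["isoform1"]]))

test_that("every domain of the reference classifies as complete against itself", {
  aln <- global_align(ref, ref)
  for (d in seq_len(nrow(bundle$domains))) {
    st <- classify_domain(aln, bundle$domains[d, ])
    expect_equal(st$category, "complete", info = bundle$domains$name[d])
    expect_equal(st$coverage, 1)
  }
  expect_error(classify_domain(aln, list(name = "x", start = 1, end = 1e4)),
               "outside the reference")
})

test_that("domain categories match the construction truth for all isoforms", {
  for (id in names(bundle$isoforms)) {
    iso <- bundle$isoforms[[id]]
    aln <- global_align(ref, stats::setNames(iso$sequence, id))
    for (d in seq_len(nrow(bundle$domains))) {
      got <- classify_domain(aln, bundle$domains[d, ])
      want <- truth_domain_status(iso, bundle$domains[d, ])
      expect_equal(got$category, want$category,
                   info = paste(id, bundle$domains$name[d]))
    }
  }
})

test_that("N-terminal truncation degrades categories monotonically", {
  ## progressively deleting the query prefix can only move an N-terminal
  ## domain along complete -> n_incomplete -> missing
  rank <- c(complete = 1, alternative_n_terminus = 2, n_incomplete = 2,
            missing = 3)
  dom <- bundle$domains[bundle$domains$name == "MBD", ]
  prev <- 0
  for (cut in c(0, 50, 100, 140, 170)) {
    q <- substr(ref, cut + 1, nchar(ref))
    aln <- global_align(ref, c(q = q))
    st <- classify_domain(aln, dom)
    expect_gte(rank[[st$category]], prev)
    prev <- rank[[st$category]]
  }
  expect_equal(prev, 3)  # fully past the domain: missing
})

test_that("the domain table reproduces both expected transcriptions", {
  tab <- build_domain_table(as.list(bundle$sequences), bundle$domains,
                            bundle$references, bundle$exon_peptides)
  d3 <- compare_domain_table(tab, ext_fixture("table3_expected.tsv"))
  d4 <- compare_domain_table(tab, ext_fixture("table4_expected.tsv"))
  expect_equal(nrow(d3), 0L, info = paste(capture.output(print(d3)),
                                          collapse = "\n"))
  expect_equal(nrow(d4), 0L, info = paste(capture.output(print(d4)),
                                          collapse = "\n"))
  ## E1-like isoforms report the E1-style reference as best-scoring
  expect_equal(unname(tab$matching_ref[c("isoform2", "B5MCB4")]),
               c("isoform2", "isoform2"))
  expect_equal(unname(tab$matching_ref[["isoform1"]]), "isoform1")
})

test_that("exon presence follows provenance-labelled runs", {
  peps <- bundle$exon_peptides
  pr <- exon_provenance(c(x = bundle$sequences[["isoform2"]]), peps)
  ep <- exon_presence(pr, peps)
  expect_equal(ep$exon1$category, "present")
  expect_equal(ep$exon2$category, "absent")
  expect_equal(ep$exon3$category, "present")

  pr4 <- exon_provenance(c(x = bundle$sequences[["isoform4"]]), peps)
  ep4 <- exon_presence(pr4, peps)
  expect_equal(ep4$exon4$category, "n_incomplete")
  expect_equal(ep4$exon3$category, "absent")
})

test_that("status vocabulary renders every category and flag combination", {
  expect_equal(render_status("complete"), "✓")
  expect_equal(render_status("missing"), "-")
  expect_equal(render_status("n_incomplete"), "N-term. incompl.")
  st <- structure(list(category = "internal_gap",
                       flags = c(prefix = FALSE, interior = TRUE,
                                 suffix = TRUE)), class = "domain_status")
  expect_equal(render_status(st), "C-term. incompl, missing fragment inside")
  st$flags[["suffix"]] <- FALSE
  expect_equal(render_status(st), "missing fragment inside")
})

test_that("domain coordinate fixtures validate on read", {
  dom <- read_domain_table(ext_fixture("synthetic_domains.tsv"))
  expect_s3_class(dom, "functional_domains")
  expect_equal(nrow(dom), 15L)
  expect_true(all(dom$start <= dom$end))
  bad <- tempfile()
  writeLines(c("name\tref_isoform\tstart\tend", "MBD\tr\t1\t2"), bad)
  expect_error(read_domain_table(bad), "source")
})
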