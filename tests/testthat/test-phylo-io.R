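test_that("bundled chronogram has 18 tips, depth 80, and validates", {
  tr <- laurasiatheria_tree()
  expect_s3_class(tr, "chronogram")
  expect_equal(ape::Ntip(tr), 18L)
  depths <- famturn:::node_depths(tr)[seq_len(18L)]
  expect_equal(unname(depths), rep(80, 18L))
  expect_true(all(tr$edge.length > 0))
})

test_that("printed tree text with spaced labels parses to the fixture", {
  tr <- parse_chronogram(printed_newick())
  ref <- laurasiatheria_tree()
  expect_equal(ape::Ntip(tr), 18L)
  expect_setequal(tr$tip.label, ref$tip.label)
  expect_equal(unname(famturn:::node_depths(tr)[seq_len(18L)]), rep(80, 18L))
  # same topology and branch lengths
  expect_true(ape::all.equal.phylo(tr, ref, use.edge.length = TRUE))
})

test_that("minimal trees parse; parse-serialize-parse is the identity", {
  tr <- parse_chronogram("(A:1,B:1);")
  expect_equal(ape::Ntip(tr), 2L)
  expect_equal(max(famturn:::node_depths(tr)), 1)

  for (txt in c("(A:1,B:1);", "((A:1,B:1):1,C:2);")) {
    t1 <- parse_chronogram(txt)
    t2 <- parse_chronogram(write_chronogram(t1))
    expect_identical(t2$tip.label, t1$tip.label)
    expect_identical(t2$edge, t1$edge)
    expect_equal(t2$edge.length, t1$edge.length, tolerance = 1e-9)
  }
  tr <- laurasiatheria_tree()
  rt <- parse_chronogram(write_chronogram(tr))
  expect_equal(rt$edge.length[order(rt$edge[, 2])],
               tr$edge.length[order(tr$edge[, 2])], tolerance = 1e-9)
})

test_that("malformed, non-ultrametric and polytomous trees are rejected", {
  expect_error(parse_chronogram("((A:1,B:1:2);"), "offset")
  expect_error(parse_chronogram("(A:1,B:1));"), "offset")
  expect_error(parse_chronogram("(A:1,B:2);"), "ultrametric.*A|A.*ultrametric")
  expect_error(parse_chronogram("(A:1,B:1,C:1);"), "polytomy|unary")
  expect_error(parse_chronogram("(A:1,B:0);"), "> 0")
})

test_that("count tables round-trip and invalid cells are located", {
  tr <- tree3()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("family_id\tA\tB\tC", "F1\t2\t1\t1", "F2\t0\t0\t1"), tmp)
  tab <- read_count_table(tmp, tr)
  expect_equal(dim(tab), c(2L, 3L))
  expect_equal(unname(tab["F1", ]), c(2L, 1L, 1L))

  tab2 <- random_counts(laurasiatheria_tree(), 40, seed = 8)
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab2, tmp2)
  back <- read_count_table(tmp2, laurasiatheria_tree())
  expect_identical(unclass(back)[, ], unclass(tab2)[, ])

  writeLines(c("family_id\tA\tB\tC", "F1\t2\t-1\t1"), tmp)
  expect_error(read_count_table(tmp, tr), "F1.*B|B.*F1")
  writeLines(c("family_id\tA\tB\tX", "F1\t2\t1\t1"), tmp)
  expect_error(read_count_table(tmp, tr), "X")
  writeLines(c("family_id\tA\tB\tC", "F1\t0\t0\t0"), tmp)
  expect_error(read_count_table(tmp, tr), "nonzero")
})

test_that("trait and term tables parse with their edge cases", {
  trait <- withr::local_tempfile(fileext = ".tsv")
  sp <- laurasiatheria_tree()$tip.label
  writeLines(c("species\tcvalue", paste(sp, signif(2 + seq_along(sp) / 10, 3),
                                        sep = "\t")), trait)
  tt <- read_trait_table(trait)
  expect_length(tt, 18L)
  expect_true(all(is.finite(tt)))

  terms <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("F1\tGO:0004984,GO:0004930", "F2\t", "F3\tGO:0050911"), terms)
  tm <- read_term_map(terms)
  expect_length(tm[["F1"]], 2L)
  expect_identical(tm[["F2"]], character())
  expect_length(tm[["F3"]], 1L)

  writeLines(c("species\tv", "A\t1.0", "A\t2.0"), trait)
  expect_error(read_trait_table(trait), "duplicate")
  writeLines(c("species\tv", "A\tnot_a_number"), trait)
  expect_error(read_trait_table(trait), "unparseable")
})
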