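test_that("family origin is the MRCA of observed presence", {
  tr <- tree3()
  expect_equal(infer_family_origin(c(A = 1, B = 1, C = 0), tr),
               mrca_node(tr, c("A", "B")))
  expect_equal(infer_family_origin(c(A = 0, B = 0, C = 2), tr),
               mrca_node(tr, "C"))
  expect_error(infer_family_origin(c(A = 0, B = 0, C = 0), tr), "all-zero")

  big <- laurasiatheria_tree()
  bats <- laurasiatheria_clades()$bats
  prof <- stats::setNames(integer(18L), big$tip.label)
  prof[bats] <- 1L
  expect_equal(infer_family_origin(prof, big), mrca_node(big, bats))
})

test_that("ancestral reconstruction matches the worked examples", {
  tr <- tree3()
  a <- ancestral_counts(c(A = 2, B = 1, C = 1), tr)
  expect_equal(a$cost, 1L)
  expect_equal(a$states[4:5], c(1L, 1L))   # root and MRCA(A,B) both 1
  expect_equal(a$events$delta[a$events$child == 1L], 1L)  # one dup on A

  b <- ancestral_counts(c(A = 1, B = 1, C = 1), tr)
  expect_equal(b$cost, 0L)
  expect_equal(unique(b$states), 1L)

  d <- ancestral_counts(c(A = 2, B = 0, C = 1), tr)
  expect_equal(d$cost, 2L)
  expect_equal(d$states[4:5], c(1L, 1L))   # dup on A, family loss on B
})

test_that("parsimony equals the exhaustive minimum on small instances", {
  trees <- list(tree2(), tree3(), tree4_bal(), tree4_cat())
  set.seed(77)
  for (rep in seq_len(120L)) {
    tr <- trees[[sample.int(4L, 1L)]]
    prof <- sample(0:3, ape::Ntip(tr), replace = TRUE)
    if (all(prof == 0)) prof[1L] <- 1L
    names(prof) <- tr$tip.label
    a <- ancestral_counts(prof, tr)
    expect_identical(a$cost, as.integer(exhaustive_parsimony(prof, tr)))
    # reconstructed tips always equal observations
    expect_identical(a$states[seq_len(ape::Ntip(tr))], unname(prof))
    # per-branch |delta| sums to the cost by definition of the report
    expect_identical(sum(abs(a$events$delta)), a$cost)
  }
})

test_that("parsimony cost never exceeds the true simulated event count", {
  tr <- laurasiatheria_tree()
  m <- rate_model(tr, tied = TRUE, lam = 0.002)
  sim <- simulate_count_table(tr, m, 250, seed = 14)
  keep <- which(rowSums(sim$counts) > 0)
  nev <- table(factor(sim$events$family, levels = rownames(sim$counts)))
  for (f in keep) {
    a <- ancestral_counts(sim$counts[f, ], tr)
    expect_lte(a$cost, as.integer(nev[rownames(sim$counts)[f]]))
  }
})

test_that("branch summaries aggregate per-family events correctly", {
  tr <- tree3()
  counts <- as_family_counts(
    matrix(c(2L, 1L, 1L,
             1L, 1L, 1L,
             2L, 0L, 1L), nrow = 3L, byrow = TRUE,
           dimnames = list(c("F1", "F2", "F3"), c("A", "B", "C"))), tr)
  s <- summarize_branch_events(counts, tr)
  eA <- s[s$branch_label == "A", ]
  expect_equal(eA$duplication_events, 2L)   # F1 and F3 each duplicate on A
  eB <- s[s$branch_label == "B", ]
  expect_equal(eB$loss_events, 1L)
  expect_equal(eB$families_lost, 1L)        # F3 disappears on B
  expect_equal(eB$contracted, 1L)
  expect_true(all(s$families_lost <= s$contracted))
  expect_equal(attr(s, "root_gained"), 3L)  # all three origin at root

  s0 <- summarize_branch_events(list(), tr)
  expect_true(all(s0[, -(1:2)] == 0L))

  # no-change simulation: zero tallies everywhere
  mz <- rate_model(tr, tied = TRUE, lam = 0)
  simz <- simulate_count_table(tr, mz, 100, seed = 4)
  sz <- summarize_branch_events(as_family_counts(simz$counts, tr), tr)
  expect_true(all(sz[, -(1:2)] == 0L))
})

test_that("lineage presence filter applies absence and clade thresholds", {
  tr <- laurasiatheria_tree()
  cl <- laurasiatheria_clades()
  counts <- matrix(0L, 3L, 18L,
                   dimnames = list(c("noBat3", "oneBat", "noBat1"),
                                   tr$tip.label))
  counts["noBat3", c("F._catus", "B._taurus", "E._caballus")] <- 1L
  counts["oneBat", c("P._alecto", "F._catus", "B._taurus",
                     "E._caballus")] <- 1L
  counts["noBat1", "F._catus"] <- 1L
  tab <- as_family_counts(counts, tr)
  req <- list(cl$carnivora, cl$cetartiodactyla, cl$perissodactyla)

  expect_identical(filter_lineage_presence(tab, tr, cl$bats, req, 3L),
                   "noBat3")
  expect_false("oneBat" %in%
    filter_lineage_presence(tab, tr, cl$bats, req, 1L))
  expect_setequal(filter_lineage_presence(tab, tr, cl$bats, req, 0L),
                  c("noBat3", "noBat1"))
  expect_error(filter_lineage_presence(tab, tr, cl$bats, req, 4L),
               "min_present")
})
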