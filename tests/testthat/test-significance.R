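test_that("multiple-testing corrections match hand computations", {
  expect_equal(adjust_pvalues(rep(0.004, 10), "bonferroni")[1], 0.04)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(c(0.01, 0.4), "holm"), c(0.02, 0.4))
  expect_equal(adjust_pvalues(0.2, "sidak"), 0.2)
  for (m in c("bh", "bonferroni", "holm", "sidak"))
    expect_equal(adjust_pvalues(0.037, m), 0.037)
  expect_identical(adjust_pvalues(numeric(), "bh"), numeric())
  p <- c(0.001, 0.5, 0.9)
  expect_equal(adjust_pvalues(p, "sidak"), 1 - (1 - p) ^ 3)
  # adjusted never below raw, always within [0, 1]
  set.seed(1)
  q <- runif(20)
  for (m in c("bh", "bonferroni", "holm", "sidak")) {
    adj <- adjust_pvalues(q, m)
    expect_true(all(adj >= q - 1e-12 & adj <= 1))
  }
})

test_that("family p-values respect the pseudocount floor and the seed", {
  tr <- tree4_bal()
  m <- rate_model(tr, tied = TRUE, lam = 0.01)
  set.seed(2)
  tab <- simulate_profiles(tr, m, 40, root = "uniform", S = 8)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  rownames(tab) <- paste0("F", seq_len(nrow(tab)))
  fit <- evaluate_model(tab, tr, m, S = 8)
  pv1 <- family_pvalues(fit, n_mc = 120, seed = 5)
  pv2 <- family_pvalues(fit, n_mc = 120, seed = 5)
  expect_identical(pv1$p, pv2$p)
  expect_gte(min(pv1$p), 1 / 121)
  expect_lte(max(pv1$p), 1)
  expect_true(all(pv1$p_bh >= pv1$p - 1e-12))
  expect_error(family_pvalues(fit, n_mc = 5), "n_mc")
  expect_warning(family_pvalues(fit, n_mc = 50, seed = 1), "n_mc")
})

test_that("branch tail test hits its closed-form cases", {
  # zero rates: every branch transition is the identity, p = 1
  tr <- tree3()
  mz <- rate_model(tr, tied = TRUE, lam = 0)
  tabz <- as_family_counts(
    matrix(2L, 1L, 3L, dimnames = list("F1", c("A", "B", "C"))), tr)
  fitz <- evaluate_model(tabz, tr, mz, S = 5)
  bp <- branch_pvalues(c(A = 2, B = 2, C = 2), fitz)
  expect_equal(bp$p, rep(1, nrow(bp)))
  expect_equal(bp$parent_state, rep(2L, nrow(bp)))

  # parent 1 -> child 0 at lam = mu = 0.001, t = 100: probability-ordered
  # tail computed from the independent scalar transition form
  t100 <- parse_chronogram("(A:100,B:100);")
  m <- rate_model(t100, tied = TRUE, lam = 0.001)
  tab <- as_family_counts(
    matrix(c(0L, 1L), 1L, 2L, dimnames = list("F1", c("A", "B"))), t100)
  fit <- evaluate_model(tab, t100, m, S = 12)
  states <- ml_ancestral_states(c(A = 0, B = 1), fit)
  expect_equal(states[3L], 1L)  # root most-likely state is 1
  row <- transition_probability(1, 0:12, 0.001, 0.001, 100)
  row <- row / sum(row)
  expected_p <- sum(row[row <= row[1] + 1e-15])
  bp2 <- branch_pvalues(c(A = 0, B = 1), fit)
  expect_equal(bp2$p[bp2$branch_label == "A"], expected_p,
               tolerance = 1e-10)

  # p decreases as the size jump grows, other things equal
  M <- transition_matrix(0.001, 0.001, 100, 30)
  row5 <- M[6, ] / sum(M[6, ])
  pj <- vapply(5:10, function(c) sum(row5[row5 <= row5[c + 1] + 1e-15]), 0)
  expect_true(all(diff(pj) <= 1e-12))
})

test_that("null LRT sample is non-negative, seeded, and nesting-checked", {
  tr <- validate_chronogram(
    ape::keep.tip(laurasiatheria_tree(), laurasiatheria_clades()$owf))
  m <- rate_model(tr, tied = TRUE, lam = 0.002)
  set.seed(3)
  tab <- simulate_profiles(tr, m, 50, root = "uniform", S = 10)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  rownames(tab) <- paste0("F", seq_len(nrow(tab)))
  fit0 <- evaluate_model(tab, tr, m, S = 10)
  alt <- rate_model(tr, clades = list(pteropus = c("P._alecto",
                                                   "P._vampyrus")),
                    tied = TRUE)
  nul <- simulate_null_lrt(fit0, alt, n_sims = 12, seed = 6)
  expect_true(all(nul$sample >= -1e-6))
  expect_length(nul$sample, 12L)
  expect_equal(nul$critical, sort(nul$sample)[ceiling(0.95 * 12)])
  nul2 <- simulate_null_lrt(fit0, alt, n_sims = 12, seed = 6)
  expect_identical(nul$sample, nul2$sample)
  # a free-rate spec does not nest a tied null
  expect_error(simulate_null_lrt(fit0, rate_model(tr, tied = FALSE),
                                 n_sims = 5), "nest")
})
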