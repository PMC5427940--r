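test_that("pruning reduces to a product on a two-tip tree", {
  tr <- parse_chronogram("(A:30,B:30);")
  m <- rate_model(tr, tied = FALSE, lam = 0.003, mu = 0.002)
  r <- 2L
  ll <- family_log_likelihood(c(A = 3, B = 1), tr, m, S = 8,
                              root_prior = list(type = "point", size = r))
  direct <- log(transition_probability(r, 3, 0.003, 0.002, 30) *
                transition_probability(r, 1, 0.003, 0.002, 30))
  expect_equal(ll$per_family, direct, tolerance = 1e-12, ignore_attr = TRUE)

  # zero-rate identity with a matching point prior
  mz <- rate_model(tr, tied = TRUE, lam = 0)
  llz <- family_log_likelihood(c(A = 4, B = 4), tr, mz, S = 6,
                               root_prior = list(type = "point", size = 4))
  expect_equal(unname(llz$per_family), 0)
})

test_that("pruning equals brute-force enumeration on three-tip trees", {
  tr <- tree3()
  m <- rate_model(tr, tied = FALSE, lam = 0.05, mu = 0.08)
  for (prof in list(c(A = 2, B = 1, C = 1), c(A = 1, B = 1, C = 1),
                    c(A = 0, B = 2, C = 1), c(A = 4, B = 0, C = 1))) {
    ll <- family_log_likelihood(prof, tr, m, S = 4)
    expect_equal(unname(ll$per_family),
                 brute_force_loglik(prof, tr, 0.05, 0.08, 4),
                 tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to species order and family labels", {
  tr <- laurasiatheria_tree()
  tab <- random_counts(tr, 30, seed = 5)
  m <- rate_model(tr, tied = TRUE, lam = 0.002)
  l1 <- family_log_likelihood(tab, tr, m, S = 10)
  shuf <- tab[, sample(colnames(tab)), drop = FALSE]
  l2 <- family_log_likelihood(shuf, tr, m, S = 10)
  expect_equal(l2$total, l1$total, tolerance = 1e-12)
  relab <- tab
  rownames(relab) <- paste0("G", seq_len(nrow(tab)))
  l3 <- family_log_likelihood(relab, tr, m, S = 10)
  expect_equal(sort(l3$per_family), sort(l1$per_family), tolerance = 1e-12)
})

test_that("zero error model equals the no-error code path exactly", {
  tr <- laurasiatheria_tree()
  tab <- random_counts(tr, 25, seed = 6)
  m <- rate_model(tr, tied = FALSE, lam = 0.001, mu = 0.002)
  l0 <- family_log_likelihood(tab, tr, m, error = NULL, S = 10)
  le <- family_log_likelihood(tab, tr, m, error = error_model(0), S = 10)
  expect_identical(le$per_family, l0$per_family)
})

test_that("no-change data drives the tied estimate to zero", {
  tr <- tree3()
  tab <- as_family_counts(
    matrix(2L, 30L, 3L, dimnames = list(paste0("F", 1:30),
                                        c("A", "B", "C"))), tr)
  fit <- fit_model(tab, tr, rate_model(tr, tied = TRUE), n_restarts = 2,
                   seed = 1)
  expect_lt(fit$lam[1], 1e-6)
})

test_that("fitting is reproducible given a seed and flags convergence", {
  tr <- laurasiatheria_tree()
  m <- rate_model(tr, tied = TRUE, lam = 0.002)
  set.seed(20)
  tab <- simulate_profiles(tr, m, 150, root = "uniform", S = 10)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  rownames(tab) <- paste0("F", seq_len(nrow(tab)))
  f1 <- fit_model(tab, tr, rate_model(tr, tied = TRUE), n_restarts = 3,
                  seed = 7)
  f2 <- fit_model(tab, tr, rate_model(tr, tied = TRUE), n_restarts = 3,
                  seed = 7)
  expect_identical(f1$lam, f2$lam)
  expect_identical(f1$minus_loglik, f2$minus_loglik)
  expect_true(f1$converged)
  expect_length(f1$restarts, 3L)
})

test_that("root filter keeps families with presence on both root sides", {
  tr <- laurasiatheria_tree()
  counts <- matrix(0L, 3L, 18L,
                   dimnames = list(c("both", "batsOnly", "othersOnly"),
                                   tr$tip.label))
  counts["both", c("P._alecto", "B._taurus")] <- 1L
  counts["batsOnly", c("P._alecto", "M._davidii")] <- 1L
  counts["othersOnly", c("F._catus", "B._taurus")] <- 2L
  kept <- filter_root_families(as_family_counts(counts, tr), tr)
  expect_identical(rownames(kept), "both")
})

test_that("state cap violations and all-zero profiles error cleanly", {
  tr <- tree3()
  m <- rate_model(tr, tied = TRUE, lam = 0.001)
  expect_error(family_log_likelihood(c(A = 9, B = 1, C = 1), tr, m, S = 4),
               "S")
  expect_error(family_log_likelihood(c(A = 0, B = 0, C = 0), tr, m, S = 4),
               "all-zero")
})
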