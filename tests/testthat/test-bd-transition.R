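test_that("transition probabilities match closed forms and normalize", {
  # no events: identity
  expect_equal(transition_probability(3, 3, 0, 0, 50), 1)
  expect_equal(transition_probability(3, 2, 0, 0, 50), 0)
  # critical-case extinction: alpha = lam t / (1 + lam t)
  expect_equal(transition_probability(1, 0, 0.001, 0.001, 100), 0.1 / 1.1,
               tolerance = 1e-12)
  # normalization at adequate truncation
  expect_gte(sum(transition_probability(2, 0:50, 0.0008, 0.0008, 80)),
             1 - 1e-9)
  # absorbing zero
  expect_equal(transition_probability(0, 0, 0.01, 0.02, 10), 1)
  expect_equal(transition_probability(0, 1, 0.01, 0.02, 10), 0)
  expect_error(transition_probability(1, 0, 0.01, 0.02, -1))
})

test_that("matrix builder agrees with the scalar survivor-sum route", {
  for (par in list(c(0.002, 0.001), c(0.001, 0.003), c(0.001, 0.001),
                   c(0, 0.01), c(0.01, 0), c(0, 0))) {
    M <- transition_matrix(par[1], par[2], 80, 15)
    for (s in c(0L, 1L, 2L, 7L, 15L))
      expect_equal(M[s + 1, ],
                   transition_probability(s, 0:15, par[1], par[2], 80),
                   tolerance = 1e-12)
    expect_true(all(M >= 0 & M <= 1))
  }
  # pure death is binomial thinning
  M <- transition_matrix(0, 0.01, 50, 8)
  expect_equal(M[6, 3], stats::dbinom(2, 5, exp(-0.5)), tolerance = 1e-12)
  expect_equal(rowSums(M), rep(1, 9), tolerance = 1e-12)
})

test_that("simulated dynamics match birth-death theory", {
  # extinction on a single branch vs alpha = lam t/(1 + lam t)
  t100 <- parse_chronogram("(A:100,B:100);")
  m100 <- rate_model(t100, tied = TRUE, lam = 0.001)
  s100 <- simulate_count_table(t100, m100, 20000,
                               root_dist = list(dist = "point", size = 1),
                               seed = 8)
  expect_equal(mean(s100$counts[, "A"] == 0), 0.1 / 1.1, tolerance = 0.08)
  # mean dynamics: E[c] = s exp((lam - mu) t), both regimes
  expect_equal(mean(s100$counts), 1, tolerance = 0.03)
  tg <- parse_chronogram("(A:80,B:80);")
  mg <- rate_model(tg, tied = FALSE, lam = 0.004, mu = 0.002)
  sg <- simulate_count_table(tg, mg, 8000,
                             root_dist = list(dist = "point", size = 2),
                             seed = 9)
  expect_equal(mean(sg$counts), 2 * exp(0.002 * 80), tolerance = 0.05)
})

test_that("observation channel has the stated form and row sums", {
  expect_equal(observation_probability(5, 5, 0), 1)
  expect_equal(observation_probability(5, 4, 0.2), 0.1)
  expect_equal(observation_probability(5, 6, 0.2), 0.1)
  expect_equal(observation_probability(0, 0, 0.2), 0.9)
  expect_equal(observation_probability(0, 1, 0.2), 0.1)
  expect_equal(observation_probability(5, 3, 0.2), 0)
  for (true in 0:6)
    expect_equal(sum(observation_probability(true, 0:20, 0.3)), 1)
  expect_error(observation_probability(1, 1, 1), "eps")
  expect_error(observation_probability(1, 1, -0.1), "eps")
})

test_that("error corruption reproduces the channel frequencies", {
  tab <- matrix(5L, 100000L, 1L, dimnames = list(NULL, "A"))
  obs <- corrupt_with_error(tab, error_model(c(A = 0.2)), seed = 3)
  f <- table(factor(obs, levels = 3:7)) / nrow(tab)
  expect_equal(as.numeric(f[c("4", "5", "6")]), c(0.1, 0.8, 0.1),
               tolerance = 0.05)
  zer <- corrupt_with_error(matrix(0L, 50000L, 1L,
                                   dimnames = list(NULL, "A")),
                            error_model(c(A = 0.3)), seed = 4)
  expect_true(all(zer >= 0L))
  expect_equal(mean(zer == 1L), 0.15, tolerance = 0.05)
  same <- corrupt_with_error(tab, error_model(c(A = 0)), seed = 5)
  expect_identical(same, tab)
})
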