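#' Estimate annotation error by profile likelihood
#'
#' Searches the +/-1 observation-error probability `eps` that maximises the
#' model likelihood, jointly refitting the birth-death rates at every
#' candidate (no prior on the error distribution). `scope = "global"` fits
#' one error shared by all species using a halving grid
#' `{0, eps_max/2^k}` refined by golden-section search around the best grid
#' point. `scope = "per_species"` starts every species at the global
#' optimum and then cycles species, profiling each error with the others
#' held fixed, until no estimate changes by more than `tol_eps`.
#'
#' @param table A `family_counts` matrix.
#' @param tree A `chronogram`.
#' @param model_spec A `rate_model` specification.
#' @param scope `"global"` or `"per_species"`.
#' @param eps_max Upper end of the search grid.
#' @param n_restarts Optimiser restarts for each inner rate fit (warm
#'   starts make 1-2 sufficient).
#' @param seed Seed for restart jitter.
#' @param tol_eps Convergence tolerance on eps.
#' @param max_cycles Maximum species cycles in per-species mode.
#' @param ... Passed to [fit_model()].
#' @return A list of class `error_fit`: `error` (the fitted
#'   [error_model()]), `fit` (rates refitted at the estimated error),
#'   `profile` (data frame of eps values and minus log-likelihoods
#'   examined, global mode).
#' @export
estimate_error <- function(table, tree, model_spec,
                           scope = c("global", "per_species"),
                           eps_max = 0.5, n_restarts = 2, seed = NULL,
                           tol_eps = 1e-3, max_cycles = 5, ...) {
  scope <- match.arg(scope)
  counts <- table[, tree$tip.label, drop = FALSE]
  S <- max(counts) + 10L
  warm <- new.env()
  warm$start <- NULL
  eval_eps <- function(epsvec) {
    em <- if (all(epsvec == 0)) NULL else error_model(epsvec)
    f <- fit_model(counts, tree, model_spec, error = em,
                   n_restarts = n_restarts, seed = seed, S = S,
                   start = warm$start, ...)
    warm$start <- c(f$lam, if (!model_spec$tied) f$mu)
    f
  }
  species <- tree$tip.label

  profile_one <- function(make_eps) {
    grid <- c(0, eps_max / 2 ^ (6:0))
    fits <- lapply(grid, function(e) eval_eps(make_eps(e)))
    nll <- vapply(fits, function(f) f$minus_loglik, 0)
    b <- which.min(nll)
    lo <- grid[max(1L, b - 1L)]
    hi <- grid[min(length(grid), b + 1L)]
    gold <- golden_section(function(e) eval_eps(make_eps(e))$minus_loglik,
                           lo, hi, tol = tol_eps)
    cand_e <- c(grid, gold$x)
    cand_n <- c(nll, gold$fx)
    best <- which.min(cand_n)
    list(eps = cand_e[best],
         profile = data.frame(eps = cand_e, minus_lnL = cand_n))
  }

  if (scope == "global") {
    res <- profile_one(function(e) e)
    fit <- eval_eps(res$eps)
    return(structure(list(error = error_model(res$eps), fit = fit,
                          profile = res$profile), class = "error_fit"))
  }

  # per-species: profile each eps with the others held fixed, cycling
  glob <- profile_one(function(e) e)
  eps <- stats::setNames(rep(glob$eps, length(species)), species)
  for (cycle in seq_len(max_cycles)) {
    delta <- 0
    for (sp in species) {
      res <- profile_one(function(e) { v <- eps; v[sp] <- e; v })
      delta <- max(delta, abs(res$eps - eps[sp]))
      eps[sp] <- res$eps
    }
    if (delta <= tol_eps) break
  }
  fit <- eval_eps(eps)
  structure(list(error = error_model(eps), fit = fit, profile = NULL),
            class = "error_fit")
}

# Golden-section minimisation on [lo, hi]; returns best point and value.
golden_section <- function(f, lo, hi, tol = 1e-3, max_iter = 20) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  xs <- c(x1, x2); fs <- c(f1, f2)
  iter <- 0L
  while (b - a > tol && iter < max_iter) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
      xs <- c(xs, x1); fs <- c(fs, f1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
      xs <- c(xs, x2); fs <- c(fs, f2)
    }
    iter <- iter + 1L
  }
  list(x = xs, fx = fs)
}
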