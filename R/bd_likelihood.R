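#' Specify a birth-death rate model over branch classes
#'
#' A rate model assigns every branch of the tree to a rate class and gives
#' each class a gain rate `lam` and loss rate `mu` (per gene per My). With
#' `tied = TRUE` the two are constrained equal within each class (a single
#' turnover rate, the "one-lambda" family of models); with `tied = FALSE`
#' gain and loss are free ("lambda-mu" models). Classes are defined by
#' clades: class 0 is the background and each named clade (e.g. all bats,
#' or Old World fruit bats and Yangochiroptera separately) gets its own
#' class including its stem branch.
#'
#' @param tree A `chronogram`.
#' @param clades Named list of tip-label vectors defining extra classes, or
#'   `NULL` for a single global class.
#' @param tied Logical; constrain `lam == mu` per class.
#' @param lam,mu Per-class rate vectors (recycled); may be `NULL` in a model
#'   specification destined for [fit_model()].
#' @return An object of class `rate_model`.
#' @export
rate_model <- function(tree, clades = NULL, tied = TRUE,
                       lam = NULL, mu = NULL) {
  cls <- branch_classes(tree, clades)
  K <- length(attr(cls, "class_names"))
  if (!is.null(lam)) lam <- rep_len(lam, K)
  mu <- if (tied) lam else if (!is.null(mu)) rep_len(mu, K) else NULL
  if (!is.null(lam) && (any(lam < 0) || any(mu < 0)))
    stop("rates must be >= 0", call. = FALSE)
  structure(list(edge_class = as.integer(cls),
                 class_names = attr(cls, "class_names"),
                 n_classes = K, tied = tied, lam = lam, mu = mu),
            class = "rate_model")
}

#' Specify a +/-1 annotation-error model
#'
#' @param eps Either a single global error probability or a named numeric
#'   vector with one entry per species; all values in `[0, 1)`.
#' @return An object of class `error_model`.
#' @export
error_model <- function(eps = 0) {
  if (any(eps < 0) || any(eps >= 1))
    stop("eps must be in [0, 1)", call. = FALSE)
  structure(list(eps = eps), class = "error_model")
}

eps_for_species <- function(error, species) {
  if (is.null(error)) return(stats::setNames(rep(0, length(species)), species))
  eps <- error$eps
  if (length(eps) == 1L && is.null(names(eps)))
    return(stats::setNames(rep(eps, length(species)), species))
  if (!all(species %in% names(eps)))
    stop("error model missing species: ",
         paste(setdiff(species, names(eps)), collapse = ", "), call. = FALSE)
  eps[species]
}

# Transition matrices for every edge, memoised over (class, t).
edge_transition_matrices <- function(tree, model, S) {
  key <- paste(model$edge_class, signif(tree$edge.length, 12))
  uk <- !duplicated(key)
  mats <- vector("list", nrow(tree$edge))
  cache <- list()
  for (k in seq_len(nrow(tree$edge))) {
    if (is.null(cache[[key[k]]])) {
      cl <- model$edge_class[k] + 1L
      cache[[key[k]]] <- transition_matrix(model$lam[cl], model$mu[cl],
                                           tree$edge.length[k], S)
    }
    mats[[k]] <- cache[[key[k]]]
  }
  mats
}

# Root prior over states 0..S, conditional on presence (state >= 1).
root_prior_vector <- function(root_prior, S) {
  if (is.numeric(root_prior) && length(root_prior) == S + 1L) {
    stopifnot(root_prior[1L] == 0)
    return(root_prior / sum(root_prior))
  }
  if (is.list(root_prior) && identical(root_prior$type, "point")) {
    v <- numeric(S + 1L); v[root_prior$size + 1L] <- 1
    return(v)
  }
  c(0, rep(1 / S, S))  # uniform over 1..S
}

#' Log-likelihood of family profiles under a birth-death model
#'
#' Felsenstein pruning over truncated ancestral size states `0..S`. Tip
#' partial likelihoods come from the annotation-error channel
#' ([observation_probability()]); the root combines partials under a prior
#' over root sizes conditional on presence (default uniform over `1..S`).
#' Computation is vectorised across families with per-family rescaling, so
#' many profiles are evaluated in one pass.
#'
#' @param counts A `family_counts` matrix, or a single named profile vector.
#' @param tree A `chronogram`.
#' @param model A `rate_model` with rates set.
#' @param error An `error_model`, or `NULL` for error-free observation.
#' @param S State-space cap; default max observed count + 10.
#' @param root_prior `"uniform"` (over `1..S`), a `list(type = "point",
#'   size = k)`, or a numeric prior vector of length `S + 1` with zero mass
#'   at 0.
#' @return A list of class `bd_loglik`: `per_family` (log-likelihood per
#'   family), `total`, `S`, and `root_posterior` (families x states matrix
#'   of posterior root-size probabilities).
#' @export
family_log_likelihood <- function(counts, tree, model, error = NULL,
                                  S = NULL, root_prior = "uniform") {
  if (!is.matrix(counts)) {
    counts <- matrix(align_profile(counts, tree), nrow = 1L,
                     dimnames = list("family", tree$tip.label))
  }
  counts <- counts[, tree$tip.label, drop = FALSE]
  if (any(rowSums(counts) == 0))
    stop("all-zero profile: family not observed", call. = FALSE)
  if (is.null(S)) S <- max(counts) + 10L
  if (max(counts) > S)
    stop("state cap S = ", S, " below max observed count ", max(counts),
         "; increase S", call. = FALSE)
  if (is.null(model$lam)) stop("rate_model has no rates set", call. = FALSE)
  pr <- root_prior_vector(root_prior, S)
  res <- prune_loglik(counts, tree, model, error, S, pr)
  post <- res$root_partial * rep(pr, each = nrow(counts))
  post <- post / rowSums(post)
  structure(list(per_family = res$loglik, total = sum(res$loglik),
                 S = S, root_posterior = post), class = "bd_loglik")
}

# Core batched pruning. counts: n x ntip integer matrix (cols in tip order).
# Thin wrapper over the compiled recursion; prune_loglik_r is the reference
# R implementation kept for cross-checking.
prune_loglik <- function(counts, tree, model, error, S, prior) {
  post <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  eps <- eps_for_species(error, tree$tip.label)
  storage.mode(counts) <- "integer"
  res <- .prune_core(counts, tree$edge[post, , drop = FALSE],
                     tree$edge.length[post],
                     as.integer(model$edge_class[post]),
                     as.numeric(model$lam), as.numeric(model$mu),
                     as.numeric(eps), as.integer(S), as.numeric(prior))
  list(loglik = res$loglik, root_partial = res$root_partial)
}

prune_loglik_r <- function(counts, tree, model, error, S, prior) {
  ntip <- length(tree$tip.label)
  nf <- nrow(counts)
  eps <- eps_for_species(error, tree$tip.label)
  mats <- edge_transition_matrices(tree, model, S)
  post <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  nn <- ntip + tree$Nnode
  partial <- vector("list", nn)
  scale <- numeric(nf)
  tip_partial <- function(tip) {
    obs <- counts[, tip]
    if (eps[tip] == 0) {
      P <- matrix(0, nf, S + 1L)
      P[cbind(seq_len(nf), obs + 1L)] <- 1
    } else {
      O <- observation_matrix(eps[tip], S)
      P <- t(O[, obs + 1L, drop = FALSE])
    }
    P
  }
  for (k in post) {
    p <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
    Lc <- if (ch <= ntip) tip_partial(ch) else partial[[ch]]
    msg <- Lc %*% t(mats[[k]])
    if (is.null(partial[[p]])) partial[[p]] <- msg
    else {
      partial[[p]] <- partial[[p]] * msg
      m <- partial[[p]][cbind(seq_len(nf), max.col(partial[[p]]))]
      m[m <= 0] <- 1  # dead family rows stay zero; logged as -Inf at root
      partial[[p]] <- partial[[p]] / m
      scale <- scale + log(m)
    }
    if (ch > ntip) partial[ch] <- list(NULL)  # free; keep list indices
  }
  root <- ntip + 1L
  lik <- drop(partial[[root]] %*% prior)
  list(loglik = log(lik) + scale, root_partial = partial[[root]])
}

# P(every tip observes 0 | model, prior): conditioning constant for fits on
# observed (non-extinct) families.
prob_all_zero <- function(tree, model, error, S, prior) {
  z <- matrix(0L, 1L, length(tree$tip.label),
              dimnames = list("z", tree$tip.label))
  res <- prune_loglik(z, tree, model, error, S, prior)
  exp(res$loglik)
}

#' Fit a birth-death rate model by maximum likelihood
#'
#' Maximises the summed per-family log-likelihood over the model's per-class
#' rates with Nelder-Mead (Brent for a single parameter) in log-rate space,
#' from `n_restarts` starts jittered around a moment-based initial value.
#' By default the likelihood is conditioned on a family being observed at
#' all (at least one nonzero tip), which removes the ascertainment bias of
#' analysing only surviving families. Families should already be restricted
#' to those present at the focal root (see [filter_root_families()]).
#'
#' @param table A `family_counts` matrix.
#' @param tree A `chronogram`.
#' @param model_spec A `rate_model` (rates may be unset; used for classes
#'   and the tied flag).
#' @param error An `error_model` or `NULL`.
#' @param n_restarts Number of jittered optimiser restarts.
#' @param seed Integer seed for the restart jitter.
#' @param S State cap (default max count + 10).
#' @param condition_on_observed Condition the likelihood on non-extinction
#'   of the observed profile.
#' @param start Optional numeric start for the rates (per-class lam, then
#'   per-class mu when free).
#' @param root_prior Root-size prior passed to the pruning (see
#'   [family_log_likelihood()]); the default uniform prior over `1..S` is
#'   deliberately uninformative about root sizes.
#' @param control List: `reltol` passed to the optimiser.
#' @return An object of class `fit_result`: fitted `model`, `lam`, `mu`,
#'   `minus_loglik`, `per_family` log-likelihoods, `restarts` (per-restart
#'   minus log-likelihoods), `converged` (best two restarts within 1e-4),
#'   `S`, `n_families`, and the `error` model used.
#' @export
fit_model <- function(table, tree, model_spec, error = NULL,
                      n_restarts = 5, seed = NULL, S = NULL,
                      condition_on_observed = TRUE, start = NULL,
                      root_prior = "uniform", control = list()) {
  counts <- table[, tree$tip.label, drop = FALSE]
  if (is.null(S)) S <- max(counts) + 10L
  prior <- root_prior_vector(root_prior, S)
  K <- model_spec$n_classes
  tied <- model_spec$tied
  npar <- if (tied) K else 2L * K
  reltol <- if (is.null(control$reltol)) 1e-8 else control$reltol

  # the conditioning constant P(all tips observe 0) rides along as one
  # extra all-zero pseudo-profile in the same pruning pass
  nf <- nrow(counts)
  counts_aug <- if (condition_on_observed)
    rbind(counts, 0L) else counts
  negll <- function(logpar) {
    lam <- exp(logpar[seq_len(K)])
    mu <- if (tied) lam else exp(logpar[K + seq_len(K)])
    m <- model_spec; m$lam <- lam; m$mu <- mu
    res <- prune_loglik(counts_aug, tree, m, error, S, prior)
    ll <- sum(res$loglik[seq_len(nf)])
    if (condition_on_observed)
      ll <- ll - nf * log1p(-exp(res$loglik[nf + 1L]))
    if (!is.finite(ll)) 1e12 else -ll
  }

  if (is.null(start)) {
    r0 <- moment_start(counts, tree)
    start <- rep(r0, npar)
  } else start <- rep_len(start, npar)
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  restarts <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    jit <- if (r == 1L) rep(1, npar) else exp(stats::runif(npar, log(0.5),
                                                           log(1.5)))
    p0 <- log(start * jit)
    opt <- if (npar == 1L)
      stats::optim(p0, negll, method = "Brent", lower = log(1e-8),
                   upper = log(1), control = list(reltol = reltol))
    else
      stats::optim(p0, negll, method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = 2000L))
    restarts[r] <- opt$value
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  srt <- sort(restarts)
  converged <- n_restarts < 2L || (srt[2L] - srt[1L]) < 1e-4
  lam <- exp(best$par[seq_len(K)])
  mu <- if (tied) lam else exp(best$par[K + seq_len(K)])
  m <- model_spec; m$lam <- lam; m$mu <- mu
  ll <- family_log_likelihood(counts, tree, m, error, S = S,
                              root_prior = root_prior)
  structure(list(model = m, lam = stats::setNames(lam, m$class_names),
                 mu = stats::setNames(mu, m$class_names),
                 minus_loglik = best$value,
                 per_family = ll$per_family,
                 root_posterior = ll$root_posterior,
                 restarts = restarts, converged = converged,
                 S = S, n_families = nrow(counts), error = error,
                 condition_on_observed = condition_on_observed,
                 table = counts, tree = tree),
            class = "fit_result")
}

# Moment-based starting turnover rate: within-family cross-tip variance
# scales like 2 * size * rate * depth under the tied model.
moment_start <- function(counts, tree, floor = 1e-5, cap = 0.05) {
  depth <- max(node_depths(tree)[seq_len(length(tree$tip.label))])
  v <- mean(apply(counts, 1L, stats::var))
  m <- max(mean(counts), 0.1)
  r0 <- v / (2 * m * depth)
  min(max(r0, floor), cap)
}

#' Evaluate a model at fixed rates
#'
#' Builds a `fit_result` for a model whose rates are already known (no
#' optimisation) -- useful for significance machinery that takes a fitted
#' model, for likelihood comparisons at published rates, and for
#' calibration studies under a known truth.
#'
#' @inheritParams fit_model
#' @param model A `rate_model` with rates set.
#' @return A `fit_result` (with `restarts` empty and `converged = TRUE`).
#' @export
evaluate_model <- function(table, tree, model, error = NULL, S = NULL,
                           condition_on_observed = TRUE) {
  counts <- table[, tree$tip.label, drop = FALSE]
  if (is.null(S)) S <- max(counts) + 10L
  ll <- family_log_likelihood(counts, tree, model, error, S = S)
  nll <- -ll$total
  if (condition_on_observed) {
    prior <- root_prior_vector("uniform", S)
    p0 <- prob_all_zero(tree, model, error, S, prior)
    nll <- nll + nrow(counts) * log1p(-p0)
  }
  structure(list(model = model,
                 lam = stats::setNames(model$lam, model$class_names),
                 mu = stats::setNames(model$mu, model$class_names),
                 minus_loglik = nll, per_family = ll$per_family,
                 root_posterior = ll$root_posterior,
                 restarts = numeric(0), converged = TRUE,
                 S = S, n_families = nrow(counts), error = error,
                 condition_on_observed = condition_on_observed,
                 table = counts, tree = tree),
            class = "fit_result")
}

#' Keep families present at the tree root
#'
#' Retains families whose origin (MRCA of observed presence) is the root
#' itself, i.e. families with at least one member on both sides of the
#' root split -- the root-presence condition applied before model fitting.
#'
#' @param table A `family_counts` matrix.
#' @param tree A `chronogram`.
#' @return The filtered `family_counts` matrix.
#' @export
filter_root_families <- function(table, tree) {
  root <- length(tree$tip.label) + 1L
  kids <- tree$edge[tree$edge[, 1L] == root, 2L]
  sides <- lapply(kids, function(k) tree$tip.label[tips_under(tree, k)])
  keep <- rowSums(table[, sides[[1L]], drop = FALSE]) > 0 &
    rowSums(table[, sides[[2L]], drop = FALSE]) > 0
  table[keep, , drop = FALSE]
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Birth-death fit:", if (x$model$tied) "tied (lambda = mu)"
      else "free lambda/mu", "\n")
  cat("  classes:", paste(x$model$class_names, collapse = ", "), "\n")
  cat("  lambda: ", paste(signif(x$lam, 4), collapse = ", "), "\n")
  cat("  mu:     ", paste(signif(x$mu, 4), collapse = ", "), "\n")
  cat("  -lnL:   ", format(x$minus_loglik), " (", x$n_families,
      " families)\n", sep = "")
  cat("  restarts agree:", x$converged, "\n")
  invisible(x)
}

#' Model fit report with AIC
#'
#' @param fits Named list of `fit_result` objects (names are model labels,
#'   e.g. `"1-lambda"`, `"2-lambdamu"`).
#' @return Data frame: model, n_parameters, minus_lnL, AIC.
#' @export
fit_report <- function(fits) {
  stopifnot(is.list(fits), !is.null(names(fits)))
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    k <- length(f$lam) * (if (f$model$tied) 1L else 2L)
    data.frame(model = nm, n_parameters = k, minus_lnL = f$minus_loglik,
               AIC = 2 * k + 2 * f$minus_loglik)
  })
  do.call(rbind, rows)
}
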