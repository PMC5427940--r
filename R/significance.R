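#' Simulate family profiles by transition-matrix sampling
#'
#' Fast simulator used by the Monte-Carlo significance machinery: draws
#' root sizes, walks the tree sampling each child state from the truncated
#' transition matrix of its branch, then (optionally) passes tip counts
#' through the annotation-error channel. For simulation with a recorded
#' per-event log, see [simulate_count_table()].
#'
#' @param tree A `chronogram`.
#' @param model A `rate_model` with rates.
#' @param n Number of profiles.
#' @param root Root sizes: a vector of length `n`, or a single size
#'   recycled, or `"uniform"` to draw from the uniform prior over `1..S`.
#' @param error An `error_model` or `NULL`.
#' @param S State cap.
#' @return Integer matrix `n x ntip` of observed tip counts (columns in
#'   tip-label order).
#' @export
simulate_profiles <- function(tree, model, n, root = "uniform",
                              error = NULL, S = 25L) {
  ntip <- length(tree$tip.label)
  mats <- edge_transition_matrices(tree, model, S)
  states <- matrix(0L, n, ntip + tree$Nnode)
  rootn <- ntip + 1L
  states[, rootn] <- if (identical(root, "uniform"))
    sample.int(S, n, replace = TRUE)
  else rep_len(as.integer(root), n)
  for (k in reorder_edges_preorder(tree)) {
    p <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
    Tm <- mats[[k]]
    ps <- states[, p]
    for (s in unique(ps)) {
      idx <- which(ps == s)
      pr <- Tm[s + 1L, ]
      states[idx, ch] <- sample.int(S + 1L, length(idx), replace = TRUE,
                                    prob = pr) - 1L
    }
  }
  obs <- states[, seq_len(ntip), drop = FALSE]
  colnames(obs) <- tree$tip.label
  eps <- eps_for_species(error, tree$tip.label)
  if (any(eps > 0)) obs <- corrupt_matrix(obs, eps)
  obs
}

#' Monte-Carlo per-family p-values for accelerated evolution
#'
#' For each family, simulates `n_mc` replicate families under the fitted
#' model and reports the pseudocounted tail probability
#' `p = (1 + #\{simulated log-lik <= observed\}) / (1 + n_mc)`. Small
#' p-values flag families whose size configuration is unlikely under the
#' random gain-and-loss process. Benjamini-Hochberg adjusted values are
#' appended.
#'
#' Two root-size schemes are available for the replicates. `"prior"`
#' (default) draws roots from the model's root prior, making each family
#' exchangeable with its replicates, so the p-values are exactly
#' calibrated (uniform under the null up to Monte-Carlo discreteness).
#' `"posterior"` draws roots from the family's conditional root-size
#' posterior, which focuses the test on deviations beyond what the
#' family's own root size explains -- closer in spirit to conditioning on
#' family size, but only approximately calibrated.
#'
#' @param fit A `fit_result` from [fit_model()].
#' @param n_mc Simulations per family (>= 100 recommended; < 10 is an
#'   error).
#' @param seed Integer seed.
#' @param chunk Families per simulation batch (memory/speed trade-off).
#' @param root `"prior"` or `"posterior"` (see Details).
#' @return Data frame: `family`, `loglik`, `p`, `p_bh`.
#' @export
family_pvalues <- function(fit, n_mc = 1000, seed = NULL, chunk = 64L,
                           root = c("prior", "posterior")) {
  root <- match.arg(root)
  if (n_mc < 10) stop("n_mc < 10: too few simulations", call. = FALSE)
  if (n_mc < 100) warning("n_mc < 100: p-values will be coarse")
  tree <- fit$tree
  counts <- fit$table
  nf <- nrow(counts)
  S <- fit$S
  if (!is.null(seed)) set.seed(seed)
  obs_ll <- fit$per_family
  prior <- root_prior_vector("uniform", S)
  p <- numeric(nf)
  for (lo in seq(1L, nf, by = chunk)) {
    hi <- min(lo + chunk - 1L, nf)
    idx <- lo:hi
    nb <- length(idx)
    roots <- if (root == "prior")
      sample.int(S, nb * n_mc, replace = TRUE)
    else unlist(lapply(idx, function(i)
      sample.int(S + 1L, n_mc, replace = TRUE,
                 prob = fit$root_posterior[i, ]) - 1L))
    sim <- simulate_profiles(tree, fit$model, nb * n_mc, root = roots,
                             error = fit$error, S = S)
    ll <- prune_loglik(sim, tree, fit$model, fit$error, S, prior)$loglik
    llm <- matrix(ll, nrow = nb, byrow = TRUE)
    p[idx] <- (1 + rowSums(llm <= obs_ll[idx])) / (1 + n_mc)
  }
  data.frame(family = rownames(counts), loglik = obs_ll, p = p,
             p_bh = adjust_pvalues(p, "bh"))
}

#' Most-likely ancestral sizes under a fitted model
#'
#' Max-product (Viterbi) analogue of the pruning recursion: returns the
#' jointly most probable assignment of ancestral family sizes given the
#' observed profile, the fitted rates and the error channel.
#'
#' @param profile Named per-species counts for one family.
#' @param fit A `fit_result`.
#' @return Integer vector of states over all nodes (tips hold their
#'   most-likely true count, which equals the observation when the error
#'   is zero).
#' @export
ml_ancestral_states <- function(profile, fit) {
  tree <- fit$tree
  S <- fit$S
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  prof <- align_profile(profile, tree)
  eps <- eps_for_species(fit$error, tree$tip.label)
  mats <- edge_transition_matrices(tree, fit$model, S)
  logM <- lapply(mats, function(m) log(m))
  # delta[node, s] = max log-prob of subtree below node given state s
  delta <- matrix(0, nn, S + 1L)
  for (tip in seq_len(ntip))
    delta[tip, ] <- log(observation_probability(0:S, prof[tip], eps[tip]))
  back <- vector("list", nrow(tree$edge))
  post <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  for (k in post) {
    p <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
    m <- logM[[k]] + rep(delta[ch, ], each = S + 1L)   # [s, c]
    back[[k]] <- max.col(m, ties.method = "first")
    delta[p, ] <- delta[p, ] + m[cbind(seq_len(S + 1L), back[[k]])]
  }
  root <- ntip + 1L
  prior <- log(root_prior_vector("uniform", S))
  states <- integer(nn)
  states[root] <- which.max(delta[root, ] + prior) - 1L
  for (k in rev(post)) {
    p <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
    states[ch] <- back[[k]][states[p] + 1L] - 1L
  }
  states
}

#' Exact per-branch transition tail test
#'
#' For each branch, computes a two-tailed probability-ordering test on the
#' size change: given the parent's most-likely state `s`, the p-value is
#' the total probability of all child states no more probable than the
#' child's state under the branch's transition distribution
#' (`p = sum over c' with P(c'|s) <= P(c|s)`). Branches with small p carry
#' unusually large changes for the fitted rates.
#'
#' @param profile Named per-species counts for one family.
#' @param fit A `fit_result`.
#' @return Data frame: `branch_child_node`, `branch_label`, `parent_state`,
#'   `child_state`, `p`.
#' @export
branch_pvalues <- function(profile, fit) {
  tree <- fit$tree
  states <- ml_ancestral_states(profile, fit)
  mats <- edge_transition_matrices(tree, fit$model, fit$S)
  nE <- nrow(tree$edge)
  p <- numeric(nE)
  for (k in seq_len(nE)) {
    s <- states[tree$edge[k, 1L]]
    cst <- states[tree$edge[k, 2L]]
    row <- mats[[k]][s + 1L, ]
    row <- row / sum(row)
    p[k] <- sum(row[row <= row[cst + 1L] + 1e-15])
  }
  data.frame(branch_child_node = tree$edge[, 2L],
             branch_label = node_label(tree, tree$edge[, 2L]),
             parent_state = states[tree$edge[, 1L]],
             child_state = states[tree$edge[, 2L]],
             p = p)
}

#' Simulation-built null distribution for a likelihood-ratio test
#'
#' Simulates `n_sims` datasets under the fitted null model (same number of
#' families; all-zero profiles are rejected and redrawn), fits both the
#' null and the nesting alternative to each, and returns the sample of
#' `2 * (lnL_alt - lnL_null)` together with its empirical 95th-percentile
#' critical value (order statistic at `ceiling(0.95 n)`), replacing the
#' asymptotic chi-squared reference. The alternative must nest the null
#' (same tied flag, at least as many classes).
#'
#' @param fit_null A `fit_result` for the null model.
#' @param alt_spec A `rate_model` specification nesting the null.
#' @param n_sims Number of simulated datasets.
#' @param seed Integer seed.
#' @param n_restarts Restarts for the per-dataset fits (warm-started).
#' @param level Tail level for the critical value.
#' @return List of class `lrt_null`: `sample`, `critical`, `n_sims`,
#'   `level`, `seed`.
#' @export
simulate_null_lrt <- function(fit_null, alt_spec, n_sims = 1000,
                              seed = NULL, n_restarts = 1, level = 0.95) {
  if (alt_spec$tied != fit_null$model$tied ||
      alt_spec$n_classes < fit_null$model$n_classes)
    stop("alternative model does not nest the null", call. = FALSE)
  tree <- fit_null$tree
  nf <- fit_null$n_families
  S <- fit_null$S
  if (!is.null(seed)) set.seed(seed)
  stat <- numeric(n_sims)
  for (i in seq_len(n_sims)) {
    sim <- simulate_profiles(tree, fit_null$model, nf, root = "uniform",
                             error = fit_null$error, S = S)
    while (any(z <- rowSums(sim) == 0)) {
      sim[z, ] <- simulate_profiles(tree, fit_null$model, sum(z),
                                    root = "uniform", error = fit_null$error,
                                    S = S)
    }
    rownames(sim) <- paste0("sim", seq_len(nf))
    stat[i] <- lrt_stat(sim, tree, fit_null$model, alt_spec,
                        error = fit_null$error,
                        n_restarts = n_restarts,
                        start = fit_null$lam[1L])
  }
  crit <- sort(stat)[ceiling(level * n_sims)]
  structure(list(sample = stat, critical = crit, n_sims = n_sims,
                 level = level, seed = seed), class = "lrt_null")
}

#' Observed likelihood-ratio statistic between nested models
#'
#' @param table A `family_counts` matrix.
#' @param tree A `chronogram`.
#' @param null_spec,alt_spec `rate_model` specifications (alternative nests
#'   the null).
#' @param error An `error_model` or `NULL`.
#' @param n_restarts Restarts per fit.
#' @param start Optional rate start.
#' @return `2 * (lnL_alt - lnL_null)`, floored at 0.
#' @export
lrt_stat <- function(table, tree, null_spec, alt_spec, error = NULL,
                     n_restarts = 1, start = NULL) {
  f0 <- fit_model(table, tree, null_spec, error = error,
                  n_restarts = n_restarts, start = start)
  f1 <- fit_model(table, tree, alt_spec, error = error,
                  n_restarts = n_restarts, start = f0$lam[1L])
  max(0, 2 * (f0$minus_loglik - f1$minus_loglik))
}

#' Multiple-testing corrections
#'
#' Standard corrections with outputs clamped to `[0, 1]`:
#' Bonferroni (`m p`), Holm step-down, Sidak (`1 - (1-p)^m`) and
#' Benjamini-Hochberg step-up (FDR).
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param method One of `"bonferroni"`, `"holm"`, `"sidak"`, `"bh"`.
#' @return Adjusted p-values, same length (empty in, empty out).
#' @export
adjust_pvalues <- function(pvals,
                           method = c("bh", "bonferroni", "holm", "sidak")) {
  method <- match.arg(method)
  if (!length(pvals)) return(numeric())
  stopifnot(all(pvals >= 0 & pvals <= 1))
  if (method == "sidak") return(pmin(1, 1 - (1 - pvals) ^ length(pvals)))
  stats::p.adjust(pvals, method = c(bh = "BH", bonferroni = "bonferroni",
                                    holm = "holm")[[method]])
}
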