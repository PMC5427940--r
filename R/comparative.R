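#' Phylogenetic independent contrasts
#'
#' Felsenstein's pruning algorithm on a binary tree: at each internal node
#' with daughters `i, j` carrying values `x_i, x_j` on (corrected) branch
#' lengths `b_i, b_j`, the standardized contrast is
#' `(x_i - x_j) / sqrt(b_i + b_j)`, the node value is the
#' `1/b`-weighted average of the daughters, and the node's own branch is
#' extended by `b_i b_j / (b_i + b_j)`. Under Brownian motion the
#' contrasts are independent with variance equal to the Brownian rate.
#'
#' @param tree A binary `chronogram`.
#' @param trait Named numeric vector with a value for every tip.
#' @return A list of class `contrast_set`: `contrasts` (named by internal
#'   node number, length `ntips - 1`), `node_values`, and
#'   `corrected_lengths` (per node, after extension).
#' @export
pic_contrasts <- function(tree, trait) {
  ntip <- length(tree$tip.label)
  missing_sp <- setdiff(tree$tip.label, names(trait))
  if (length(missing_sp))
    stop("missing trait value for species: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  if (any(!is.finite(trait[tree$tip.label])))
    stop("non-finite trait value", call. = FALSE)
  nn <- ntip + tree$Nnode
  x <- numeric(nn)
  x[seq_len(ntip)] <- trait[tree$tip.label]
  blen <- numeric(nn)
  blen[tree$edge[, 2L]] <- tree$edge.length
  post <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  contrasts <- numeric(0)
  # visit each internal node once both children are resolved (postorder
  # edge pairs share the parent consecutively on a binary tree)
  kids <- split(tree$edge[post, 2L], tree$edge[post, 1L])
  order_nodes <- unique(tree$edge[post, 1L])
  for (p in order_nodes) {
    ij <- kids[[as.character(p)]]
    i <- ij[1L]; j <- ij[2L]
    bi <- blen[i]; bj <- blen[j]
    contrasts[as.character(p)] <- (x[i] - x[j]) / sqrt(bi + bj)
    x[p] <- (x[i] / bi + x[j] / bj) / (1 / bi + 1 / bj)
    blen[p] <- blen[p] + bi * bj / (bi + bj)
  }
  structure(list(contrasts = contrasts, node_values = x,
                 corrected_lengths = blen), class = "contrast_set")
}

#' Correlate two tip-level quantities, raw or phylogenetically corrected
#'
#' Raw mode: Spearman's rank correlation with average ranks for ties and a
#' seeded permutation p-value (two-sided) -- appropriate at small numbers
#' of species where the large-sample approximation is unreliable. PIC
#' mode: both variables are converted to independent contrasts on the same
#' tree and correlated by Pearson's product-moment *through the origin*
#' (contrasts have arbitrary sign, so no intercept is fitted), with a
#' two-sided t-test on `n - 1` degrees of freedom for `n` contrasts.
#'
#' @param x,y Named numeric vectors over the same species (>= 4).
#' @param method `"spearman"` or `"pearson"` (raw mode only).
#' @param use_pic Apply independent contrasts first (requires `tree`).
#' @param tree A `chronogram` (PIC mode).
#' @param n_perm Permutations for the raw-mode p-value.
#' @param seed Integer seed for the permutation test.
#' @return List: `estimate`, `p`, `n`, `method`, `use_pic`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson"),
                      use_pic = FALSE, tree = NULL, n_perm = 10000,
                      seed = NULL) {
  method <- match.arg(method)
  if (use_pic) {
    stopifnot(!is.null(tree))
    cx <- pic_contrasts(tree, x)$contrasts
    cy <- pic_contrasts(tree, y)$contrasts
    n <- length(cx)
    if (n < 4L) stop("need >= 4 contrasts", call. = FALSE)
    r <- sum(cx * cy) / sqrt(sum(cx ^ 2) * sum(cy ^ 2))
    df <- n - 1L
    tstat <- r * sqrt(df / (1 - r ^ 2))
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    return(list(estimate = r, p = p, n = n, method = "pearson_origin",
                use_pic = TRUE))
  }
  common <- intersect(names(x), names(y))
  if (is.null(names(x))) {
    stopifnot(length(x) == length(y))
    xv <- x; yv <- y
  } else {
    xv <- x[common]; yv <- y[common]
  }
  n <- length(xv)
  if (n < 4L) stop("need >= 4 paired observations", call. = FALSE)
  est_fun <- if (method == "spearman")
    function(a, b) stats::cor(rank(a), rank(b))
  else stats::cor
  est <- est_fun(xv, yv)
  if (!is.null(seed)) set.seed(seed)
  perm <- replicate(n_perm, est_fun(xv, sample(yv)))
  p <- (1 + sum(abs(perm) >= abs(est) - 1e-12)) / (1 + n_perm)
  list(estimate = est, p = p, n = n, method = method, use_pic = FALSE)
}

#' Genome-size (C-value) imputation by genus average
#'
#' Returns the species' own C-value when present in the database;
#' otherwise the arithmetic mean over congeners, identified by the first
#' underscore-delimited token of the species label. Errors when no
#' congener exists.
#'
#' @param species Species label (genus parseable as the first token).
#' @param cvalue_db Named numeric vector of C-values keyed by species.
#' @return List: `value`, `source` (`"direct"` or `"genus_mean"`),
#'   `n_congeners`.
#' @export
impute_cvalue <- function(species, cvalue_db) {
  if (species %in% names(cvalue_db))
    return(list(value = unname(cvalue_db[species]), source = "direct",
                n_congeners = NA_integer_))
  genus <- strsplit(species, "_", fixed = TRUE)[[1L]][1L]
  db_genus <- vapply(strsplit(names(cvalue_db), "_", fixed = TRUE),
                     `[[`, "", 1L)
  hits <- cvalue_db[db_genus == genus]
  if (!length(hits))
    stop("no congeners of '", species, "' (genus '", genus,
         "') in the C-value database; supply a value manually",
         call. = FALSE)
  list(value = mean(hits), source = "genus_mean",
       n_congeners = length(hits))
}

#' Per-tip turnover statistics from a fitted model and event mapping
#'
#' For each terminal branch, reports the expected numbers of gene gains
#' and losses under the fitted per-class rates (`rate x mean parent size x
#' branch duration` per gene), and the parsimony-based average expansion
#' (mean copy-number change over families). These are the per-species
#' quantities correlated against genome size.
#'
#' @param fit A `fit_result`.
#' @param summary Branch-event summary from [summarize_branch_events()].
#' @return Data frame keyed by species: `expected_gains`,
#'   `expected_losses`, `mean_expansion`.
#' @export
tip_turnover <- function(fit, summary) {
  tree <- fit$tree
  ntip <- length(tree$tip.label)
  tipe <- match(seq_len(ntip), tree$edge[, 2L])
  cls <- fit$model$edge_class[tipe] + 1L
  t <- tree$edge.length[tipe]
  mean_size <- colMeans(fit$table)[tree$tip.label]
  nf <- fit$n_families
  s <- summary[match(seq_len(ntip), summary$branch_child_node), ]
  data.frame(species = tree$tip.label,
             expected_gains = fit$lam[cls] * mean_size * t,
             expected_losses = fit$mu[cls] * mean_size * t,
             mean_expansion = (s$duplication_events - s$loss_events) / nf)
}
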