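#' Background population for a branch enrichment test
#'
#' The population for testing enrichment on a branch is the set of families
#' inferred to be present (copy number >= 1) at the *parent* node of that
#' branch: only families that existed before the branch could expand,
#' contract or disappear along it.
#'
#' @param maps List of `ancestral_states` reconstructions (named by family
#'   id, or names taken from their profiles' source order), or a
#'   `family_counts` matrix (reconstructions computed on the fly).
#' @param tree A `chronogram`.
#' @param branch_child Node number identifying the branch by its child end.
#' @return Character vector of family ids present at the parent node.
#' @export
define_population <- function(maps, tree, branch_child) {
  e <- which(tree$edge[, 2L] == branch_child)
  if (!length(e))
    stop("no branch with child node ", branch_child, " on this tree",
         call. = FALSE)
  if (inherits(maps, "family_counts") || is.matrix(maps)) {
    ids <- rownames(maps)
    maps <- lapply(seq_len(nrow(maps)), function(i)
      ancestral_counts(maps[i, ], tree))
    names(maps) <- ids
  }
  parent <- tree$edge[e, 1L]
  present <- vapply(maps, function(m) m$states[parent] >= 1L, logical(1L))
  names(maps)[present]
}

#' Term over-representation by Fisher's exact test
#'
#' One-sided hypergeometric tail test per term: with `N` population
#' families, `K` of them annotated with the term, and a study set of size
#' `n` containing `k` annotated families, `p = P(X >= k)` for
#' `X ~ Hypergeom(N, K, n)`. Terms with zero population count are skipped
#' (they carry no information and would only inflate the correction
#' burden). Expansion and contraction sets are tested in separate calls.
#' Bonferroni, Holm and Sidak adjusted columns use `m` = number of terms
#' actually tested.
#'
#' @param study_set Character vector of family ids (must be a subset of
#'   `population_set`).
#' @param population_set Character vector of family ids.
#' @param term_map Named list: family id -> character vector of terms.
#'   Entries for families outside the population are ignored (with a
#'   warning when they are absent from it entirely).
#' @return Data frame of class `enrichment_table`, sorted by raw p:
#'   `term`, `k`, `n`, `K`, `N`, `p`, `p_bonferroni`, `p_holm`, `p_sidak`.
#' @export
fisher_enrichment <- function(study_set, population_set, term_map) {
  if (!all(study_set %in% population_set))
    stop("study set is not a subset of the population", call. = FALSE)
  extra <- setdiff(names(term_map), population_set)
  if (length(extra))
    warning(length(extra), " term-map families not in the population; ",
            "ignored")
  tm <- term_map[intersect(names(term_map), population_set)]
  N <- length(unique(population_set))
  n <- length(unique(study_set))
  long_fam <- rep(names(tm), lengths(tm))
  long_term <- unlist(tm, use.names = FALSE)
  if (!length(long_term))
    return(empty_enrichment())
  Ktab <- table(term = long_term)
  ktab <- table(term = long_term[long_fam %in% study_set])
  terms <- names(Ktab)
  K <- as.integer(Ktab)
  k <- as.integer(ktab[terms]); k[is.na(k)] <- 0L
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = terms, k = k, n = n, K = K, N = N, p = p,
                    p_bonferroni = adjust_pvalues(p, "bonferroni"),
                    p_holm = adjust_pvalues(p, "holm"),
                    p_sidak = adjust_pvalues(p, "sidak"))
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", class(out))
  out
}

empty_enrichment <- function() {
  out <- data.frame(term = character(), k = integer(), n = integer(),
                    K = integer(), N = integer(), p = numeric(),
                    p_bonferroni = numeric(), p_holm = numeric(),
                    p_sidak = numeric())
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Study sets of expanding / contracting / lost families on a branch
#'
#' Classifies each family by its parsimony-reconstructed copy-number change
#' along a branch: `expanded` (child > parent), `contracted`
#' (child < parent), `lost` (parent > 0, child = 0).
#'
#' @inheritParams define_population
#' @return List of character vectors: `expanded`, `contracted`, `lost`,
#'   `population` (families present at the parent node).
#' @export
branch_change_sets <- function(maps, tree, branch_child) {
  if (inherits(maps, "family_counts") || is.matrix(maps)) {
    ids <- rownames(maps)
    maps <- lapply(seq_len(nrow(maps)), function(i)
      ancestral_counts(maps[i, ], tree))
    names(maps) <- ids
  }
  e <- which(tree$edge[, 2L] == branch_child)
  if (!length(e))
    stop("no branch with child node ", branch_child, call. = FALSE)
  parent <- tree$edge[e, 1L]
  ps <- vapply(maps, function(m) m$states[parent], integer(1L))
  cs <- vapply(maps, function(m) m$states[branch_child], integer(1L))
  pop <- names(maps)[ps >= 1L]
  list(expanded = names(maps)[ps >= 1L & cs > ps],
       contracted = names(maps)[ps >= 1L & cs < ps],
       lost = names(maps)[ps > 0L & cs == 0L],
       population = pop)
}
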