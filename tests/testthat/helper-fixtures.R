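# Shared fixtures and independent oracles, built in code.

tree2 <- function() parse_chronogram("(A:1,B:1);")
tree3 <- function() parse_chronogram("((A:1,B:1):1,C:2);")
tree4_bal <- function() parse_chronogram("((A:1,B:1):1,(C:1,D:1):1);")
tree4_cat <- function() parse_chronogram("(((A:1,B:1):1,C:2):1,D:3);")

# the reference chronogram as printed, abbreviated binomials with spaces
printed_newick <- function() {
  paste0("(((R. aegyptiacus: 24, (P. alecto: 12, P. vampyrus: 12): 12): 42,",
         " (M. natalensis: 45, (E. fuscus: 25, (M. davidii: 14,",
         " (M. lucifugus: 9, M. brandtii: 9): 5): 11): 20): 21): 14,",
         " ((F. catus: 55, (C. l. familiaris: 46, (M. p. furo: 40,",
         " A. melanoleuca: 40): 6): 9): 24, (E. caballus: 78,",
         " (V. pacos: 65, (S. scrofa: 64, (T. truncatus: 56,",
         " (O. aries: 26, B. taurus: 26): 30): 8): 1): 13): 1): 1);")
}

# brute-force tree likelihood: sum over all ancestral size assignments,
# uniform root prior over 1..S, transition probs from the scalar closed form
brute_force_loglik <- function(profile, tree, lam, mu, S) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  prof <- profile[tree$tip.label]
  grid <- as.matrix(expand.grid(rep(list(0:S), nint)))
  Tm <- lapply(seq_len(nrow(tree$edge)), function(k)
    transition_matrix(lam, mu, tree$edge.length[k], S))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    st <- c(prof, grid[g, ])
    if (st[ntip + 1L] == 0L) next       # root prior mass only on 1..S
    pr <- 1 / S
    for (k in seq_len(nrow(tree$edge)))
      pr <- pr * Tm[[k]][st[tree$edge[k, 1L]] + 1L, st[tree$edge[k, 2L]] + 1L]
    tot <- tot + pr
  }
  log(tot)
}

# exhaustive Wagner parsimony: minimum total |change| over all internal
# assignments with states 0..max(profile)+1
exhaustive_parsimony <- function(profile, tree) {
  prof <- profile[tree$tip.label]
  Smax <- max(prof) + 1L
  grid <- as.matrix(expand.grid(rep(list(0:Smax), tree$Nnode)))
  costs <- apply(grid, 1L, function(g) {
    st <- c(prof, g)
    sum(abs(st[tree$edge[, 2L]] - st[tree$edge[, 1L]]))
  })
  min(costs)
}

# hypergeometric over-representation tail by direct combinatorial summation
hyper_tail_sum <- function(k, K, N, n) {
  ks <- k:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# true copy number of every family at `node`, replayed from a synthetic
# study's root sizes and exact event log (independent of any inference)
replay_events_to_node <- function(study, node) {
  tr <- study$tree
  root <- length(tr$tip.label) + 1L
  path <- integer(0)                       # child nodes on root -> node path
  cur <- node
  while (cur != root) {
    path <- c(path, cur)
    cur <- tr$edge[tr$edge[, 2L] == cur, 1L]
  }
  ev <- study$events
  vapply(rownames(study$counts_true), function(f) {
    sel <- ev$family == f & ev$branch_child_node %in% path
    study$root_sizes[[f]] +
      sum(ev$type[sel] == "gain") - sum(ev$type[sel] == "loss")
  }, integer(1))
}

# random small count table on a tree
random_counts <- function(tree, n_fam, max_count = 4, seed = 1) {
  set.seed(seed)
  ntip <- length(tree$tip.label)
  m <- matrix(sample(0:max_count, n_fam * ntip, replace = TRUE),
              nrow = n_fam, dimnames = list(paste0("F", seq_len(n_fam)),
                                            tree$tip.label))
  m[rowSums(m) == 0, 1L] <- 1L
  storage.mode(m) <- "integer"
  as_family_counts(m, tree)
}
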