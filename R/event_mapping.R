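#' Infer the origin node of a gene family
#'
#' A hierarchical orthologous group is the set of genes descended from a
#' single ancestral gene, so its origin is taken as the most recent common
#' ancestor of all species in which it is observed. Ancestral copy numbers
#' are fixed to zero outside the subtree rooted here.
#'
#' @param profile Named integer vector of per-species counts (names = tip
#'   labels), or an unnamed vector in tip-label order of `tree`.
#' @param tree A `chronogram`.
#' @return The node number of the origin (a tip number for single-species
#'   families).
#' @export
infer_family_origin <- function(profile, tree) {
  profile <- align_profile(profile, tree)
  present <- tree$tip.label[profile > 0]
  if (!length(present))
    stop("family not observed: all-zero profile", call. = FALSE)
  mrca_node(tree, present)
}

align_profile <- function(profile, tree) {
  if (!is.null(names(profile))) {
    idx <- match(tree$tip.label, names(profile))
    if (anyNA(idx))
      stop("profile missing species: ",
           paste(tree$tip.label[is.na(idx)], collapse = ", "), call. = FALSE)
    profile <- profile[idx]
  } else if (length(profile) != length(tree$tip.label)) {
    stop("unnamed profile length != number of tips", call. = FALSE)
  }
  as.integer(profile)
}

#' Ancestral copy numbers by linear-cost (Wagner) parsimony
#'
#' Sankoff dynamic programming over integer states `0..S` with transition
#' cost `|child - parent|`, i.e. every per-copy gain or loss weighted
#' equally. `S` is the family's maximum observed count + 1. The family's
#' origin (MRCA of presence) is fixed first; nodes outside the origin
#' subtree are 0 and the origin state is constrained to be >= 1. Ties are
#' broken deterministically: among minimum-cost states the one closest to
#' the parent's chosen state wins, then the smaller count; at the origin,
#' the smallest minimum-cost state >= 1.
#'
#' @inheritParams infer_family_origin
#' @return A list of class `ancestral_states` with elements `states`
#'   (integer vector over all nodes), `origin` (node number), `cost` (total
#'   parsimony cost) and `events` (data frame of per-branch copy-number
#'   changes: `child`, `delta`).
#' @export
ancestral_counts <- function(profile, tree) {
  profile <- align_profile(profile, tree)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  origin <- infer_family_origin(profile, tree)
  S <- max(profile) + 1L
  states01 <- 0:S
  sub <- nodes_under(tree, origin)

  post <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  # cost[node, s+1] = min cost of subtree below node given node state s
  cost <- matrix(0, nrow = nn, ncol = S + 1L)
  for (tip in seq_len(ntip)) {
    cost[tip, ] <- Inf
    cost[tip, profile[tip] + 1L] <- 0
  }
  # child-to-parent messages, postorder within the origin subtree
  absdiff <- abs(outer(states01, states01, "-"))   # [parent s, child c]
  for (k in post) {
    ch <- tree$edge[k, 2L]; p <- tree$edge[k, 1L]
    if (!(ch %in% sub) || !(p %in% sub)) next
    m <- apply(absdiff + rep(cost[ch, ], each = S + 1L), 1L, min)
    cost[p, ] <- cost[p, ] + m
  }
  # origin state: smallest minimum-cost state >= 1
  best_state <- if (origin <= ntip) profile[origin] else {
    cands <- cost[origin, -1L]
    which(cands == min(cands))[1L]                 # state value (>=1)
  }
  states <- integer(nn)
  states[origin] <- best_state
  # top-down assignment, preorder within the subtree
  pre <- rev(post)
  for (k in pre) {
    p <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
    if (!(p %in% sub) || !(ch %in% sub)) next
    sc <- cost[ch, ] + abs(states01 - states[p])
    mn <- min(sc)
    tied <- states01[sc == mn]
    # closest to parent's chosen state, then smaller count
    d <- abs(tied - states[p])
    tied <- tied[d == min(d)]
    states[ch] <- min(tied)
  }
  deltas <- states[tree$edge[, 2L]] - states[tree$edge[, 1L]]
  events <- data.frame(child = tree$edge[, 2L], delta = deltas)
  structure(list(states = states, origin = origin,
                 cost = sum(abs(deltas)), events = events,
                 profile = profile),
            class = "ancestral_states")
}

#' Per-branch gain/duplication/loss summary over a family set
#'
#' Aggregates parsimony reconstructions into the per-branch tallies used in
#' branch-annotated tree figures: families gained (origin on the branch),
#' families lost (parent count > 0, child count = 0), duplication events
#' (sum of positive copy-number changes), loss events (sum of negative
#' changes), and counts of expanded / contracted families.
#'
#' @param maps A list of `ancestral_states` objects, or a `family_counts`
#'   matrix (reconstructions are computed).
#' @param tree The common `chronogram`.
#' @return A data frame keyed by `branch_child_node` (plus `branch_label`)
#'   with columns `families_gained`, `families_lost`, `duplication_events`,
#'   `loss_events`, `expanded`, `contracted`. A `root_gained` attribute
#'   counts families whose origin is the root itself (no subtending branch).
#' @export
summarize_branch_events <- function(maps, tree) {
  if (inherits(maps, "family_counts") || is.matrix(maps)) {
    maps <- lapply(seq_len(nrow(maps)), function(i)
      ancestral_counts(maps[i, ], tree))
  }
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  nn <- ntip + tree$Nnode
  for (m in maps)
    if (length(m$states) != nn)
      stop("summarize_branch_events: reconstruction on a different tree",
           call. = FALSE)
  gained <- lost <- dup <- del <- exp_ <- con <- integer(nedge)
  child_of_edge <- tree$edge[, 2L]
  edge_of_child <- match(seq_len(nn), child_of_edge)
  root <- ntip + 1L
  root_gained <- 0L
  for (m in maps) {
    if (m$origin == root) root_gained <- root_gained + 1L
    else {
      e <- edge_of_child[m$origin]
      gained[e] <- gained[e] + 1L
    }
    d <- m$events$delta
    pstate <- m$states[tree$edge[, 1L]]
    cstate <- m$states[tree$edge[, 2L]]
    dup <- dup + pmax(0L, d)
    del <- del + pmax(0L, -d)
    exp_ <- exp_ + (d > 0L)
    con <- con + (d < 0L)
    lost <- lost + (pstate > 0L & cstate == 0L)
  }
  lab <- node_label(tree, child_of_edge)
  out <- data.frame(branch_child_node = child_of_edge,
                    branch_label = lab,
                    families_gained = gained,
                    families_lost = lost,
                    duplication_events = dup,
                    loss_events = del,
                    expanded = exp_,
                    contracted = con)
  attr(out, "root_gained") <- root_gained
  out
}

node_label <- function(tree, nodes) {
  ntip <- length(tree$tip.label)
  ifelse(nodes <= ntip, tree$tip.label[nodes], paste0("node", nodes))
}

#' Filter families by clade absence/presence pattern
#'
#' Retains families with zero counts at every tip of `absent_clade` and a
#' nonzero count in at least `min_present` of the `required_clades` (a clade
#' counts as present when any of its tips has a nonzero count). Used to
#' separate genuine lineage-specific gene loss from clustering artefacts:
#' e.g. families with no bat gene but members in at least three other
#' laurasiatherian lineages.
#'
#' @param table A `family_counts` matrix.
#' @param tree A `chronogram`.
#' @param absent_clade Node number, or character vector of tip labels, whose
#'   tips must all be zero.
#' @param required_clades List of node numbers or tip-label vectors.
#' @param min_present Minimum number of required clades with presence.
#' @return Character vector of retained family ids.
#' @export
filter_lineage_presence <- function(table, tree, absent_clade,
                                    required_clades, min_present) {
  if (min_present > length(required_clades))
    stop("min_present (", min_present, ") exceeds number of required clades (",
         length(required_clades), ")", call. = FALSE)
  clade_tips <- function(x) {
    node <- if (is.character(x)) mrca_node(tree, x) else x
    tree$tip.label[tips_under(tree, node)]
  }
  abs_tips <- clade_tips(absent_clade)
  absent_ok <- rowSums(table[, abs_tips, drop = FALSE]) == 0
  pres <- vapply(required_clades, function(cl)
    rowSums(table[, clade_tips(cl), drop = FALSE]) > 0,
    logical(nrow(table)))
  if (is.null(dim(pres))) pres <- matrix(pres, nrow = nrow(table))
  keep <- absent_ok & rowSums(pres) >= min_present
  rownames(table)[keep]
}

#' Write the per-branch event summary to TSV
#'
#' @param summary Data frame from [summarize_branch_events()].
#' @param path Output path.
#' @export
write_branch_events <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
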