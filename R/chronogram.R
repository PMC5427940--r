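#' Parse and validate a dated species tree (chronogram)
#'
#' Reads a rooted, strictly binary, ultrametric Newick tree with branch
#' lengths in million years (My). Whitespace inside tip labels (as in trees
#' printed with abbreviated binomials such as `"R. aegyptiacus"`) is
#' normalised to underscores so that tip names match the species columns of
#' count, trait and term tables unambiguously.
#'
#' @param newick_text A Newick string (or a length-1 character vector holding
#'   one). Branch lengths are mandatory on every edge except the root.
#' @param tol Relative tolerance for the ultrametricity check on root-to-tip
#'   path sums. Integer My branch lengths validate exactly; the default
#'   absorbs float noise in user-supplied trees.
#' @return An object of class `c("chronogram", "phylo")` -- an
#'   \pkg{ape}-compatible tree that has passed validation.
#' @examples
#' tr <- parse_chronogram("(A:1,B:1);")
#' ape::Ntip(tr)
#' @export
parse_chronogram <- function(newick_text, tol = 1e-6) {
  stopifnot(is.character(newick_text), length(newick_text) == 1L)
  txt <- normalize_newick_labels(newick_text)
  check_newick_syntax(txt)
  tree <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse error: unreadable tree string",
                          call. = FALSE)
  validate_chronogram(tree, tol = tol)
}

#' Read a chronogram from a Newick file
#'
#' @param path Path to a Newick file containing one tree.
#' @inheritParams parse_chronogram
#' @return A `chronogram` object.
#' @export
read_chronogram <- function(path, tol = 1e-6) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_chronogram(txt, tol = tol)
}

#' Validate an existing phylo object as a chronogram
#'
#' Checks that the tree is rooted, strictly binary, has strictly positive
#' branch lengths, unique non-empty tip labels, and is ultrametric within
#' `tol` (relative). Polytomies are rejected rather than resolved: both the
#' branch-event report and independent contrasts assume a binary tree.
#'
#' @param tree A `phylo` object.
#' @inheritParams parse_chronogram
#' @return The tree with class `c("chronogram", "phylo")`.
#' @export
validate_chronogram <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("chronogram validation: tree has no branch lengths", call. = FALSE)
  ntip <- length(tree$tip.label)
  if (ntip < 2L)
    stop("chronogram validation: need at least 2 tips", call. = FALSE)
  if (any(tree$tip.label == "" | is.na(tree$tip.label)))
    stop("chronogram validation: empty tip label", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("chronogram validation: duplicate tip label '",
         tree$tip.label[duplicated(tree$tip.label)][1L], "'", call. = FALSE)
  # strictly binary: every internal node has exactly two children
  kids <- tabulate(tree$edge[, 1L], nbins = ntip + tree$Nnode)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  bad <- internal[kids[internal] != 2L]
  if (length(bad))
    stop("chronogram validation: polytomy or unary node at internal node ",
         bad[1L], " (", kids[bad[1L]], " children)", call. = FALSE)
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length <= 0))
    stop("chronogram validation: all branch lengths must be > 0",
         call. = FALSE)
  d <- node_depths(tree)[seq_len(ntip)]
  dev <- abs(d - max(d)) / max(d)
  if (any(dev > tol))
    stop("chronogram validation: tree not ultrametric; deviating tip '",
         tree$tip.label[which.max(dev)], "' (root-to-tip ",
         format(d[which.max(dev)]), " vs max ", format(max(d)), ")",
         call. = FALSE)
  class(tree) <- unique(c("chronogram", class(tree)))
  tree
}

# Root-to-node path lengths (preorder accumulation); names by node number.
node_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  depth <- numeric(nn)
  ord <- reorder_edges_preorder(tree)
  for (k in ord) {
    p <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
    depth[ch] <- depth[p] + tree$edge.length[k]
  }
  depth
}

# Edge indices in an order where every parent precedes its children.
reorder_edges_preorder <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  rev(tr)
}

# Light syntax pre-check so malformed input reports a character offset.
check_newick_syntax <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unbalanced ')' at character offset ", i,
             call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("Newick parse error: ", depth, " unclosed '(' by character offset ",
         length(chars), call. = FALSE)
  invisible(TRUE)
}

# Drop whitespace around structural characters, then turn remaining
# whitespace (necessarily inside labels) into underscores.
normalize_newick_labels <- function(txt) {
  txt <- gsub("\\s*([(),:;])\\s*", "\\1", txt)
  txt <- gsub("\\s+", "_", trimws(txt))
  txt
}

#' Serialise a chronogram back to Newick
#'
#' @param tree A `chronogram`/`phylo` object.
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_chronogram <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' The bundled 18-taxon laurasiatherian chronogram
#'
#' A time-calibrated species tree for 8 bats (3 Old World fruit bats, 5
#' yangochiropterans) and 10 other laurasiatherian mammals, with integer
#' branch lengths in million years and a uniform root-to-tip depth of 80 My.
#' The root is the most recent common ancestor of Scrotifera (bats +
#' carnivores + perissodactyls + cetartiodactyls). This is the reference
#' tree used by the synthetic-study generator and the worked examples.
#'
#' @return A `chronogram` object with 18 tips.
#' @examples
#' tr <- laurasiatheria_tree()
#' ape::Ntip(tr)
#' @export
laurasiatheria_tree <- function() {
  path <- system.file("extdata", "laurasiatheria_chronogram.nwk",
                      package = "famturn", mustWork = TRUE)
  read_chronogram(path)
}

#' Named clades of the bundled chronogram
#'
#' Convenience tip sets for the three bat groupings used throughout:
#' all bats (Chiroptera), the non-echolocating Old World fruit bats, and the
#' echolocating Yangochiroptera.
#'
#' @return A named list of character vectors of tip labels.
#' @export
laurasiatheria_clades <- function() {
  owf <- c("R._aegyptiacus", "P._alecto", "P._vampyrus")
  yango <- c("M._natalensis", "E._fuscus", "M._davidii", "M._lucifugus",
             "M._brandtii")
  carnivora <- c("F._catus", "C._l._familiaris", "M._p._furo",
                 "A._melanoleuca")
  cetartiodactyla <- c("V._pacos", "S._scrofa", "T._truncatus", "O._aries",
                       "B._taurus")
  list(bats = c(owf, yango),
       owf = owf,
       yango = yango,
       carnivora = carnivora,
       perissodactyla = "E._caballus",
       cetartiodactyla = cetartiodactyla)
}

#' Most recent common ancestor of a set of tips
#'
#' @param tree A `chronogram`/`phylo` object.
#' @param tips Character vector of tip labels (length >= 1).
#' @return The node number of the MRCA (a tip number if a single tip).
#' @export
mrca_node <- function(tree, tips) {
  stopifnot(length(tips) >= 1L)
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx))
    stop("unknown tip label(s): ", paste(tips[is.na(idx)], collapse = ", "),
         call. = FALSE)
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}

#' Tips and nodes within a clade
#'
#' `tips_under()` returns the tip numbers in the clade rooted at `node`;
#' `nodes_under()` returns all node numbers (tips and internal nodes,
#' including `node` itself).
#'
#' @param tree A `chronogram`/`phylo` object.
#' @param node A node number (tip or internal).
#' @return Sorted integer vector of node numbers.
#' @export
tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- node
  repeat {
    ch <- tree$edge[tree$edge[, 1L] %in% kids[kids > ntip], 2L]
    newkids <- setdiff(ch, kids)
    if (!length(newkids)) break
    kids <- c(kids, newkids)
  }
  sort(kids[kids <= ntip])
}

#' @rdname tips_under
#' @export
nodes_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- node
  frontier <- node
  while (length(frontier)) {
    ch <- tree$edge[tree$edge[, 1L] %in% frontier, 2L]
    out <- c(out, ch)
    frontier <- ch[ch > ntip]
  }
  sort(unique(out))
}

#' Map branches to rate classes by clade membership
#'
#' Assigns every branch (identified by its child node) a class id. Class 0 is
#' the background; each named clade in `clades` gets the next id, covering
#' all branches inside the clade plus, when `include_stem`, the stem branch
#' leading to its MRCA. Later clades override earlier ones, so nested clades
#' (e.g. fruit bats within bats) can be listed innermost-last.
#'
#' @param tree A `chronogram`.
#' @param clades Named list of character vectors of tip labels; `NULL` for a
#'   single-class (background-only) assignment.
#' @param include_stem Include the branch subtending each clade's MRCA.
#' @return Integer vector over edges (rows of `tree$edge`) of class ids,
#'   with attribute `class_names`.
#' @export
branch_classes <- function(tree, clades = NULL, include_stem = TRUE) {
  cls <- integer(nrow(tree$edge))
  nm <- "background"
  if (!is.null(clades)) {
    stopifnot(is.list(clades), !is.null(names(clades)))
    for (i in seq_along(clades)) {
      node <- mrca_node(tree, clades[[i]])
      members <- nodes_under(tree, node)
      sel <- if (include_stem) tree$edge[, 2L] %in% members
             else tree$edge[, 1L] %in% members
      cls[sel] <- i
      nm <- c(nm, names(clades)[i])
    }
  }
  attr(cls, "class_names") <- nm
  cls
}
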