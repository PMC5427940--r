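#' Read a family-by-species copy-count table
#'
#' Expects a UTF-8 TSV with a header row: first column the family identifier,
#' remaining columns one species each, cells non-negative integer gene copy
#' counts. Every species column must match a tip label of `tree` exactly, and
#' every retained family must have at least one nonzero count.
#'
#' @param path Path to the TSV file.
#' @param tree Optional `chronogram` to validate species columns against.
#' @return An integer matrix (families x species) with family ids as row
#'   names, of class `family_counts`.
#' @export
read_count_table <- function(path, tree = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("count table must have a family-id column plus >=1 species column",
         call. = FALSE)
  fam <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  bad <- which(!is.finite(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad))
    stop("count table: non-integer or negative value at family '",
         fam[bad[1L, 1L]], "', species '", colnames(mat)[bad[1L, 2L]], "'",
         call. = FALSE)
  storage.mode(mat) <- "integer"
  rownames(mat) <- fam
  as_family_counts(mat, tree = tree)
}

#' Validate a counts matrix as a family count table
#'
#' @param mat Integer matrix, families in rows (row names = family ids),
#'   species in columns.
#' @param tree Optional `chronogram` whose tip labels the columns must match.
#' @return The matrix with class `family_counts`.
#' @export
as_family_counts <- function(mat, tree = NULL) {
  stopifnot(is.matrix(mat))
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop("count table: family ids must be unique row names", call. = FALSE)
  if (is.null(colnames(mat)))
    stop("count table: species names required as column names", call. = FALSE)
  if (any(mat < 0)) stop("count table: negative count", call. = FALSE)
  if (any(rowSums(mat) == 0))
    stop("count table: family '",
         rownames(mat)[which(rowSums(mat) == 0)[1L]],
         "' has no nonzero entry", call. = FALSE)
  if (!is.null(tree)) {
    unknown <- setdiff(colnames(mat), tree$tip.label)
    if (length(unknown))
      stop("count table: species not on tree: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  class(mat) <- c("family_counts", class(mat))
  mat
}

#' Write a family count table to TSV
#'
#' @param mat A `family_counts` matrix.
#' @param path Output path.
#' @export
write_count_table <- function(mat, path) {
  df <- data.frame(family_id = rownames(mat), as.data.frame(unclass(mat)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read species trait and family term-annotation tables
#'
#' The trait table is a two-column TSV with header (`species<TAB>value`);
#' the term table maps `family_id<TAB>term1,term2,...` (no header). Term rows
#' for families absent from an accompanying count table are kept but flagged
#' with a warning at use time, not here; trait species missing from the tree
#' are fatal only when contrasts are requested.
#'
#' @param trait_path Path to the trait TSV (or `NULL` to skip).
#' @param term_path Path to the term TSV (or `NULL` to skip).
#' @return A list with elements `traits` (named numeric vector by species)
#'   and `terms` (named list of character vectors by family id).
#' @export
read_annotation_tables <- function(trait_path = NULL, term_path = NULL) {
  traits <- if (!is.null(trait_path)) read_trait_table(trait_path) else NULL
  terms <- if (!is.null(term_path)) read_term_map(term_path) else NULL
  list(traits = traits, terms = terms)
}

#' @rdname read_annotation_tables
#' @export
read_trait_table <- function(trait_path) {
  df <- utils::read.delim(trait_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("trait table needs species and value columns",
                          call. = FALSE)
  sp <- as.character(df[[1L]])
  if (anyDuplicated(sp))
    stop("trait table: duplicate species row '", sp[duplicated(sp)][1L], "'",
         call. = FALSE)
  val <- suppressWarnings(as.numeric(df[[2L]]))
  if (anyNA(val))
    stop("trait table: unparseable value for species '", sp[is.na(val)][1L],
         "'", call. = FALSE)
  stats::setNames(val, sp)
}

#' @rdname read_annotation_tables
#' @export
read_term_map <- function(term_path) {
  lines <- readLines(term_path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1L)
  terms <- lapply(parts, function(p) {
    if (length(p) < 2L || !nzchar(p[2L])) return(character())
    strsplit(p[2L], ",", fixed = TRUE)[[1L]]
  })
  stats::setNames(terms, ids)
}

#' Write a trait table / term map to TSV
#'
#' @param traits Named numeric vector by species.
#' @param path Output path.
#' @export
write_trait_table <- function(traits, path) {
  utils::write.table(data.frame(species = names(traits), value = traits),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param terms Named list of character vectors by family id.
#' @rdname write_trait_table
#' @export
write_term_map <- function(terms, path) {
  lines <- vapply(seq_along(terms), function(i)
    paste0(names(terms)[i], "\t", paste(terms[[i]], collapse = ",")), "")
  writeLines(lines, path)
  invisible(path)
}
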