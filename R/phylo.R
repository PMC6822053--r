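#' Patristic distance matrix of a single tree
#'
#' The patristic distance between two tips is the sum of branch lengths
#' along the unique path connecting them. Rows and columns are returned in
#' canonical (alphabetical) species order.
#'
#' @param tree a `phylo` object with branch lengths.
#' @return symmetric numeric matrix, zero diagonal.
#' @export
patristic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  m <- ape::cophenetic.phylo(tree)
  ord <- order(rownames(m))
  m[ord, ord]
}

#' Average patristic distances over a set of trees
#'
#' Elementwise arithmetic mean of the per-tree patristic matrices, aligned
#' by species name. All trees must share the same taxon set. Note that a
#' mean of tree metrics is generally not itself additive on any single
#' tree; the average is used as a distance summary, not a tree.
#'
#' @param trees a `multiPhylo` (e.g. from [read_tree_set()]) or list of
#'   `phylo` objects.
#' @return symmetric matrix of class `phylo_distance`, mean patristic
#'   distances in canonical species order.
#' @export
average_patristic <- function(trees) {
  trees <- validate_tree_set(trees)
  acc <- patristic_matrix(trees[[1L]])
  if (length(trees) > 1L) {
    for (i in 2L:length(trees)) {
      mi <- patristic_matrix(trees[[i]])
      acc <- acc + mi[rownames(acc), colnames(acc)]
    }
  }
  g <- acc / length(trees)
  class(g) <- c("phylo_distance", class(g))
  g
}

#' Trim two distance matrices to their shared species
#'
#' Restricts both matrices to the intersection of their species sets, in
#' identical canonical (alphabetical) order, so they can be compared by a
#' Mantel test. Species present in only one input are dropped (reported via
#' a message).
#'
#' @param m1,m2 square matrices with species dimnames.
#' @param quiet suppress the dropped-species message.
#' @return list with `m1`, `m2` (aligned), and `species` (shared set).
#' @export
align_matrices <- function(m1, m2, quiet = FALSE) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  s1 <- rownames(m1); s2 <- rownames(m2)
  if (is.null(s1) || is.null(s2)) stop("matrices must carry species names")
  shared <- sort(intersect(s1, s2))
  if (length(shared) < 3L) {
    stop("fewer than 3 shared species (", length(shared), ")")
  }
  dropped <- c(setdiff(s1, shared), setdiff(s2, shared))
  if (length(dropped) && !quiet) {
    message("align_matrices: dropping ", length(dropped),
            " unshared species: ", paste(sort(dropped), collapse = ", "))
  }
  list(m1 = m1[shared, shared], m2 = m2[shared, shared], species = shared)
}
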