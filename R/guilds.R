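#' Hierarchical clustering of the population-dynamics distance matrix
#'
#' Agglomerates species from the dynamics distance matrix into a dendrogram
#' whose branches define response guilds. Species are sorted by canonical
#' name before clustering so that equal-height merges and leaf order are
#' reproducible regardless of input order.
#'
#' @param d symmetric distance matrix (e.g. from [dynamics_distance()]),
#'   with species names as dimnames.
#' @param method agglomeration method passed to [stats::hclust()]
#'   (default `"complete"`).
#' @return an object of class `linkage_tree` (an `hclust` with the method
#'   recorded), leaves labelled by species.
#' @export
build_linkage <- function(d, method = "complete") {
  d <- as.matrix(d)
  if (any(!is.finite(d))) stop("non-finite entries in distance matrix")
  if (is.null(rownames(d))) stop("distance matrix must carry species names")
  if (max(abs(d - t(d))) > 1e-10) stop("distance matrix must be symmetric")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- hclust(as.dist(d), method = method)
  hc$dist.method <- "dynamics (1 - r)"
  class(hc) <- c("linkage_tree", "hclust")
  hc
}

#' Cut a dendrogram into response guilds
#'
#' Cuts the linkage tree either at one or more heights or into target
#' numbers of guilds `k`. Cuts at decreasing heights (or increasing k)
#' give nested, progressively finer partitions; labels within each
#' resolution are consecutive positive integers in order of first
#' appearance along the species list.
#'
#' @param tree a `linkage_tree` from [build_linkage()].
#' @param k integer vector of target guild counts, or `NULL`.
#' @param h numeric vector of cut heights, or `NULL`. Exactly one of `k`,
#'   `h` must be given.
#' @return an object of class `guild_allocation`: a list with `species` and
#'   `resolutions`, a named list mapping each resolution (e.g. `"k=4"` or
#'   `"h=1.2"`) to an integer label vector.
#' @export
cut_dendrogram <- function(tree, k = NULL, h = NULL) {
  stopifnot(inherits(tree, "hclust"))
  if (is.null(k) == is.null(h)) stop("give exactly one of k or h")
  n <- length(tree$labels)
  res <- list()
  if (!is.null(k)) {
    if (any(k < 1L | k > n)) stop("k must be in 1..", n)
    for (kk in sort(as.integer(k))) {
      res[[paste0("k=", kk)]] <- relabel_first_appearance(cutree(tree, k = kk))
    }
  } else {
    top <- max(tree$height)
    if (any(h < 0 | h > top + 1e-12)) {
      stop("h must lie in [0, ", format(top), "]")
    }
    for (hh in sort(h, decreasing = TRUE)) {
      res[[paste0("h=", format(hh))]] <-
        relabel_first_appearance(cutree(tree, h = hh))
    }
  }
  structure(list(species = tree$labels, resolutions = res),
            class = "guild_allocation")
}

relabel_first_appearance <- function(labels) {
  as.integer(factor(labels, levels = unique(labels)))
}

#' @export
print.guild_allocation <- function(x, ...) {
  sizes <- vapply(x$resolutions, function(l) length(unique(l)), integer(1))
  cat("Guild allocation for", length(x$species), "species;",
      "resolutions:", paste(names(sizes), "->", sizes, "guilds",
                            collapse = "; "), "\n")
  invisible(x)
}

#' Guild allocation as a species-by-resolution table
#' @param x a `guild_allocation`.
#' @return data.frame with a `species` column and one integer column per
#'   resolution.
#' @export
as_guild_table <- function(x) {
  stopifnot(inherits(x, "guild_allocation"))
  out <- data.frame(species = x$species, stringsAsFactors = FALSE)
  for (nm in names(x$resolutions)) out[[nm]] <- x$resolutions[[nm]]
  out
}

#' Adjusted agreement between a recovered and a true partition
#'
#' Adjusted Rand index between two labelings of the same species: 1 iff the
#' partitions are identical up to relabeling, approximately 0 for random
#' allocations, computed from the pair-counting contingency table with the
#' expected-index correction.
#'
#' @param labels integer/character vector of recovered guild labels, or a
#'   `guild_allocation` with a single resolution.
#' @param truth vector of true labels, same length/order.
#' @return adjusted Rand index in \[-1, 1\].
#' @export
guild_recovery_score <- function(labels, truth) {
  if (inherits(labels, "guild_allocation")) {
    if (length(labels$resolutions) != 1L) {
      stop("give a single-resolution allocation or a label vector")
    }
    labels <- labels$resolutions[[1L]]
  }
  if (length(labels) != length(truth)) stop("label vectors differ in length")
  tab <- table(labels, truth)
  n <- sum(tab)
  sum_comb <- function(v) sum(choose(v, 2))
  a <- sum_comb(tab)
  b <- sum_comb(rowSums(tab))
  c_ <- sum_comb(colSums(tab))
  total <- choose(n, 2)
  expected <- b * c_ / total
  max_idx <- (b + c_) / 2
  if (max_idx == expected) return(1)   # both partitions trivial
  (a - expected) / (max_idx - expected)
}

#' Export a linkage tree
#'
#' Serializes the dendrogram both as a JSON description of the merge steps
#' (heights, merged clusters, leaf order) and as a Newick string so that
#' standard tree viewers can render it.
#'
#' @param tree a `linkage_tree`.
#' @param json_path,newick_path optional output paths; if `NULL` the
#'   corresponding string is only returned.
#' @return list with elements `json` (character) and `newick` (character),
#'   invisibly if paths are given.
#' @export
export_linkage <- function(tree, json_path = NULL, newick_path = NULL) {
  stopifnot(inherits(tree, "hclust"))
  obj <- list(
    method = tree$method,
    labels = tree$labels,
    merge = unclass(tree$merge),
    height = tree$height,
    order = tree$order
  )
  json <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  phy <- ape::as.phylo(structure(unclass(tree), class = "hclust"))
  newick <- ape::write.tree(phy)
  if (!is.null(json_path)) writeLines(as.character(json), json_path)
  if (!is.null(newick_path)) writeLines(newick, newick_path)
  out <- list(json = as.character(json), newick = newick)
  if (is.null(json_path) && is.null(newick_path)) out else invisible(out)
}
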