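# independent oracles, deliberately naive and separate from the package's
# computational paths

# brute-force agglomerative clustering: returns sorted merge heights
naive_agglomerate_heights <- function(d, method = c("complete", "average",
                                                    "single")) {
  method <- match.arg(method)
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        dij <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        h <- switch(method, complete = max(dij), single = min(dij),
                    average = mean(dij))
        if (h < best_h) { best_h <- h; best <- c(j, i) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# patristic distances via shortest paths on the tree's weighted edge graph
patristic_oracle <- function(tree) {
  skip_if_not_installed("igraph")
  n_tip <- length(tree$tip.label)
  g <- igraph::graph_from_data_frame(
    data.frame(from = tree$edge[, 1], to = tree$edge[, 2]),
    directed = FALSE)
  dm <- igraph::distances(g, weights = tree$edge.length)
  ids <- as.character(seq_len(n_tip))
  out <- dm[ids, ids]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  ord <- order(tree$tip.label)
  out[ord, ord]
}

# all permutations of 1..n by simple recursion (independent of the package)
perms_oracle <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perms_oracle(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    t(apply(sub, 1, function(p) append(p, n, after = pos - 1L)))
  }))
}

# exact one-tailed Mantel p by full enumeration
mantel_exact_p_oracle <- function(m1, m2) {
  n <- nrow(m1)
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  obs <- cor(v1, m2[lt])
  pm <- perms_oracle(n)
  stats <- apply(pm, 1, function(p) cor(v1, m2[p, p][lt]))
  mean(stats >= obs - 1e-12)
}
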