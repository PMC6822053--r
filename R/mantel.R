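#' Mantel correlation between two distance matrices
#'
#' Pearson correlation of the strictly-lower-triangle entries of two
#' symmetric matrices sharing the same species order. Under joint row and
#' column permutation this correlation is a strictly increasing function of
#' the classical cross-product (sum-of-products) Mantel statistic, so
#' permutation p-values from either form are identical.
#'
#' @param m1,m2 symmetric numeric matrices, same dimension and species
#'   order, n >= 4.
#' @return Mantel r in \[-1, 1\].
#' @export
mantel_statistic <- function(m1, m2) {
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  n <- nrow(m1)
  if (n < 4L) stop("need at least 4 species")
  if (!all(dim(m1) == dim(m2))) stop("matrix dimensions differ")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2))) {
    stop("species order differs; use align_matrices() first")
  }
  lt <- lower.tri(m1)
  v1 <- m1[lt]; v2 <- m2[lt]
  if (sd(v1) == 0 || sd(v2) == 0) stop("zero variance in a matrix triangle")
  cor(v1, v2)
}

#' Permutation Mantel test with species-bootstrap confidence limits
#'
#' Tests the association between two aligned distance matrices by jointly
#' permuting the rows and columns of `m2`. The default one-tailed p-value
#' for positive association is `(\#\{r_perm >= r_obs\} + 1) / (n_perm + 1)`;
#' the +1 is the standard continuity correction for sampled permutations,
#' which also guarantees p >= 1/(n_perm + 1). When the species count is so
#' small that fewer than `n_perm` distinct permutations exist, the test
#' enumerates all n! permutations exactly (no correction needed, since the
#' full null distribution is used). Confidence limits for r come from a
#' percentile bootstrap that resamples species with replacement and
#' recomputes r on the induced submatrices (self-pairs of a duplicated
#' species are dropped).
#'
#' @param m1,m2 symmetric matrices in identical species order.
#' @param n_perm number of permutations (>= 99; default 9999).
#' @param n_boot bootstrap replicates for the confidence limits (default
#'   500; 0 disables).
#' @param seed optional integer seed making the permutations and bootstrap
#'   reproducible.
#' @param tail `"greater"` (default; positive association), `"less"` or
#'   `"two"`.
#' @return object of class `mantel_result`: list with `r_obs`, `p`,
#'   `ci_low`, `ci_high`, `n_perm` (actual permutations used), `n_boot`,
#'   `n_species`, `tail`, `exact` (logical), `seed`.
#' @export
mantel_test <- function(m1, m2, n_perm = 9999L, n_boot = 500L, seed = NULL,
                        tail = c("greater", "less", "two")) {
  tail <- match.arg(tail)
  if (n_perm < 99L) stop("n_perm must be at least 99")
  m1 <- as.matrix(m1); m2 <- as.matrix(m2)
  r_obs <- mantel_statistic(m1, m2)
  n <- nrow(m1)
  if (!is.null(seed)) set.seed(seed)
  lt <- lower.tri(m1)
  v1 <- m1[lt]

  exact <- factorial(n) <= n_perm
  if (exact) {
    perms <- all_permutations(n)
    stats <- vapply(perms, function(p) {
      cor(v1, m2[p, p][lt])
    }, numeric(1))
    n_used <- length(perms)
    p <- switch(tail,
      greater = mean(stats >= r_obs - 1e-12),
      less    = mean(stats <= r_obs + 1e-12),
      two     = mean(abs(stats) >= abs(r_obs) - 1e-12))
  } else {
    stats <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      p_idx <- sample.int(n)
      stats[b] <- cor(v1, m2[p_idx, p_idx][lt])
    }
    n_used <- n_perm
    p <- switch(tail,
      greater = (sum(stats >= r_obs - 1e-12) + 1) / (n_perm + 1),
      less    = (sum(stats <= r_obs + 1e-12) + 1) / (n_perm + 1),
      two     = (sum(abs(stats) >= abs(r_obs) - 1e-12) + 1) / (n_perm + 1))
  }

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    reps <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, replace = TRUE)
      pair_keep <- outer(idx, idx, "!=") & lower.tri(m1)
      b1 <- m1[idx, idx][pair_keep]
      b2 <- m2[idx, idx][pair_keep]
      if (length(b1) >= 3L && sd(b1) > 0 && sd(b2) > 0) {
        reps[b] <- cor(b1, b2)
      }
    }
    ci <- unname(quantile(reps, c(0.025, 0.975), na.rm = TRUE))
  }

  structure(list(r_obs = r_obs, p = p, ci_low = ci[1], ci_high = ci[2],
                 n_perm = n_used, n_boot = n_boot, n_species = n,
                 tail = tail, exact = exact, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf(
    "Mantel test (%s%s): r = %.4f, p = %.4g (n = %d species, %d permutations)\n",
    x$tail, if (x$exact) ", exact" else "", x$r_obs, x$p, x$n_species,
    x$n_perm))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  bootstrap 95%% CL: [%.4f, %.4f] (%d resamples)\n",
                x$ci_low, x$ci_high, x$n_boot))
  }
  invisible(x)
}

# all permutations of 1..n, for the exact small-n null (n <= 8 in practice)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Run a battery of Mantel tests and tabulate the results
#'
#' Applies [mantel_test()] to each named pair of matrices (aligning each
#' pair to its shared species first) and returns one row per comparison in
#' the shape of a published Mantel summary: matrix names, observed r,
#' simulated p, and the 2.5%/97.5% bootstrap confidence limits.
#'
#' @param pairs list of lists, each with elements `name1`, `name2`, `m1`,
#'   `m2`.
#' @param n_perm,n_boot,tail passed to [mantel_test()].
#' @param seed integer; each comparison uses `seed + i - 1` so rows are
#'   individually reproducible.
#' @return data.frame with columns `matrix1`, `matrix2`, `mantel_r`,
#'   `p_value`, `ci_lower`, `ci_upper`, `n_species`.
#' @export
mantel_report <- function(pairs, n_perm = 9999L, n_boot = 500L, seed = 1L,
                          tail = "greater") {
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    al <- align_matrices(pr$m1, pr$m2, quiet = TRUE)
    mt <- mantel_test(al$m1, al$m2, n_perm = n_perm, n_boot = n_boot,
                      seed = seed + i - 1L, tail = tail)
    data.frame(matrix1 = pr$name1, matrix2 = pr$name2,
               mantel_r = mt$r_obs, p_value = mt$p,
               ci_lower = mt$ci_low, ci_upper = mt$ci_high,
               n_species = mt$n_species, stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(matrix1 = character(0), matrix2 = character(0),
                      mantel_r = numeric(0), p_value = numeric(0),
                      ci_lower = numeric(0), ci_upper = numeric(0),
                      n_species = integer(0)))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
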