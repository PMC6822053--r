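#' Standardize log abundance indices per species
#'
#' Centers and scales each species' non-missing series to mean 0 and unit
#' standard deviation. Pearson correlations of interannual changes are
#' invariant to any per-species affine transform, so this choice of
#' standardization affects presentation only, not the downstream distance
#' matrix. Species whose series has zero variance cannot be standardized
#' and are dropped with a warning naming them.
#'
#' @param x an [abundance_matrix()] of log-scale indices.
#' @return an [abundance_matrix()] with each row z-scored.
#' @export
standardize_abundance <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  sds <- apply(x$values, 1, sd, na.rm = TRUE)
  const <- !is.na(sds) & sds == 0
  if (any(const)) {
    warning("excluding constant series: ",
            paste(x$species[const], collapse = ", "))
    if (sum(!const) < 2L) stop("fewer than 2 species remain")
    x <- abundance_matrix(x$values[!const, , drop = FALSE],
                          x$species[!const], x$years)
    sds <- sds[!const]
  }
  mu <- rowMeans(x$values, na.rm = TRUE)
  vals <- (x$values - mu) / sds
  abundance_matrix(vals, x$species, x$years)
}

#' Interannual changes in abundance
#'
#' For each species the change in year t is the standardized log index in
#' year t minus that of year t - 1. A change is missing iff either source
#' year is missing, so one missing index knocks out the two adjacent
#' changes. Input years y1..yn yield change years y2..yn.
#'
#' @param x an [abundance_matrix()] (typically standardized).
#' @return an object of class `change_matrix`: list with `species`,
#'   `change_years`, `values` (species x change-years, `NA` = missing).
#' @export
interannual_changes <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  n <- length(x$years)
  vals <- x$values[, 2:n, drop = FALSE] - x$values[, 1:(n - 1), drop = FALSE]
  yrs <- x$years[-1L]
  dimnames(vals) <- list(x$species, yrs)
  structure(list(species = x$species, change_years = yrs, values = vals),
            class = "change_matrix")
}

#' @export
print.change_matrix <- function(x, ...) {
  cat("Interannual change matrix:", length(x$species), "species x",
      length(x$change_years), "change years (", x$change_years[1], "-",
      x$change_years[length(x$change_years)], ")\n")
  invisible(x)
}

#' Pairwise Pearson correlation of interannual changes (complete pairs)
#'
#' Correlates every pair of species' change series using only years in
#' which both species have an observed change. Pairs with fewer than
#' `min_pairs` complete observations are too noisy to interpret and are
#' returned as `NA` rather than fabricated.
#'
#' @param changes a `change_matrix` from [interannual_changes()].
#' @param min_pairs minimum number of complete pairs per correlation
#'   (default 10; must be >= 3).
#' @return list with `r` (correlation matrix, unit diagonal) and `n_pairs`
#'   (integer matrix of complete-pair counts).
#' @export
change_correlation <- function(changes, min_pairs = 10L) {
  stopifnot(inherits(changes, "change_matrix"), min_pairs >= 3L)
  v <- t(changes$values)            # years x species
  r <- suppressWarnings(cor(v, use = "pairwise.complete.obs"))
  obs <- !is.na(changes$values)
  n_pairs <- obs %*% t(obs)
  storage.mode(n_pairs) <- "integer"
  low <- n_pairs < min_pairs
  diag(low) <- FALSE
  if (any(low)) r[low] <- NA_real_
  diag(r) <- 1
  dimnames(r) <- dimnames(n_pairs) <- list(changes$species, changes$species)
  list(r = r, n_pairs = n_pairs)
}

#' Transform a correlation matrix into a population-dynamics distance matrix
#'
#' Applies d = 1 - r, mapping perfect synchrony (r = 1) to distance 0, no
#' correlation to 1, and perfectly opposite dynamics (r = -1) to 2. The
#' result is suitable for hierarchical clustering and Mantel tests.
#'
#' @param r symmetric correlation matrix with entries in \[-1, 1\] and unit
#'   diagonal.
#' @param tol numerical tolerance for the \[-1, 1\] range check.
#' @return symmetric distance matrix of class `dynamics_distance` with zero
#'   diagonal and entries in \[0, 2\].
#' @export
to_distance <- function(r, tol = 1e-8) {
  r <- as.matrix(r)
  if (any(abs(r) > 1 + tol, na.rm = TRUE)) {
    stop("correlation entries outside [-1, 1]")
  }
  r[r > 1] <- 1
  r[r < -1] <- -1
  d <- 1 - r
  diag(d) <- 0
  class(d) <- c("dynamics_distance", class(d))
  d
}

#' Population-dynamics distance matrix from an abundance matrix
#'
#' Convenience wrapper chaining [standardize_abundance()],
#' [interannual_changes()], [change_correlation()] and [to_distance()].
#'
#' @inheritParams standardize_abundance
#' @inheritParams change_correlation
#' @param require_complete if `TRUE` (default) an error is raised when any
#'   species pair falls below `min_pairs` complete observations, since a
#'   distance matrix with holes cannot be clustered; raise data coverage or
#'   impute instead.
#' @return list with `d` (the `dynamics_distance` matrix) and `n_pairs`.
#' @export
dynamics_distance <- function(x, min_pairs = 10L, require_complete = TRUE) {
  ch <- interannual_changes(standardize_abundance(x))
  cc <- change_correlation(ch, min_pairs = min_pairs)
  if (require_complete && anyNA(cc$r)) {
    bad <- which(is.na(cc$r), arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    stop("species pairs with fewer than ", min_pairs,
         " complete observations (e.g. ",
         rownames(cc$r)[bad[1, 1]], " / ", colnames(cc$r)[bad[1, 2]],
         "); raise coverage or lower min_pairs")
  }
  list(d = to_distance(cc$r), n_pairs = cc$n_pairs)
}
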