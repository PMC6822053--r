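#' Relative national density index D
#'
#' D combines occupancy and abundance: `D_i = O_i * A_i / max_j(O_j * A_j)`,
#' where `O` is the mean number of occupied 10-km grid squares and `A` the
#' mean number of survey observations. The index scales to \[0, 1\] with
#' the most widely occurring, most frequently recorded species at exactly 1.
#'
#' @param traits a [trait_table()].
#' @return named numeric vector `D` in \[0, 1\], one entry per species.
#' @export
density_index <- function(traits) {
  oa <- traits$O * traits$A
  if (max(oa) == 0) stop("all O*A products are zero")
  setNames(oa / max(oa), traits$species)
}

#' Larval biomass provisioning index B
#'
#' `B_i = D_i * L_i / max(D * L)` with `L` the larval length in mm, under
#' the assumption that larval length is proportional to larval biomass and
#' adult density tracks larval density. Species with missing `L` get a
#' missing score (not zero); the maximum is taken over species with
#' complete inputs.
#'
#' @param traits a [trait_table()] with an `L` column.
#' @param D density index from [density_index()]; computed if `NULL`.
#' @return named numeric vector `B` in \[0, 1\], `NA` where `L` is missing.
#' @export
biomass_index <- function(traits, D = NULL) {
  if (is.null(D)) D <- density_index(traits)
  if (!"L" %in% colnames(traits)) stop("trait table has no L column")
  scale_to_max(D[traits$species] * traits$L, traits$species)
}

#' General wildflower pollination index P
#'
#' `P_i = D_i * M_i / max(D * M)` with `M` a mobility index: abundant,
#' mobile species are assumed to move more pollen between wildflower
#' patches. Missing `M` yields a missing score.
#'
#' @inheritParams biomass_index
#' @return named numeric vector `P` in \[0, 1\], `NA` where `M` is missing.
#' @export
pollination_index <- function(traits, D = NULL) {
  if (is.null(D)) D <- density_index(traits)
  if (!"M" %in% colnames(traits)) stop("trait table has no M column")
  scale_to_max(D[traits$species] * traits$M, traits$species)
}

#' Per-family pollination index P_x
#'
#' `P_x,i = D_i * M_i * X_i / max(D * M * X)` where `X_i` is 1 if species i
#' visits plant family x and 0 otherwise; the denominator is the maximum
#' over species for that family. Non-visitors score exactly 0; species with
#' missing `M` score `NA`.
#'
#' @inheritParams biomass_index
#' @param family plant family name (an `X_<family>` column must exist).
#' @return named numeric vector `P_x` in \[0, 1\].
#' @export
family_pollination_index <- function(traits, family, D = NULL) {
  if (is.null(D)) D <- density_index(traits)
  col <- paste0("X_", family)
  if (!col %in% colnames(traits)) {
    stop("no visitation column for family ", family)
  }
  if (!"M" %in% colnames(traits)) stop("trait table has no M column")
  x <- traits[[col]]
  if (all(x == 0, na.rm = TRUE)) {
    stop("no species visits family ", family, "; P_x undefined")
  }
  raw <- D[traits$species] * traits$M * x
  out <- scale_to_max(raw, traits$species)
  out[which(x == 0)] <- 0       # true zeros even if M missing elsewhere
  out
}

#' Aesthetic cultural function index C
#'
#' `C_i = Y_i / max(Y)` where `Y` is a species' mean count in a public
#' mass-participation survey. Only the `top_n` most-recorded species carry
#' a `Y` value; all others have negligible public visibility and score
#' exactly 0.
#'
#' @param traits a [trait_table()] with a `Y` column (`NA` = not among the
#'   most-recorded species).
#' @param top_n expected number of species with a `Y` score (default 18,
#'   the length of the published most-recorded list); a differing count is
#'   allowed but noted with a message.
#' @return named numeric vector `C` in \[0, 1\]; no missing values.
#' @export
cultural_index <- function(traits, top_n = 18L) {
  if (!"Y" %in% colnames(traits)) stop("trait table has no Y column")
  y <- traits$Y
  n_scored <- sum(!is.na(y))
  if (n_scored == 0) stop("no species has a public-survey count Y")
  if (n_scored != top_n) {
    message("cultural_index: ", n_scored, " species carry Y (expected ",
            top_n, ")")
  }
  out <- y / max(y, na.rm = TRUE)
  out[is.na(out)] <- 0
  setNames(out, traits$species)
}

scale_to_max <- function(raw, species) {
  mx <- suppressWarnings(max(raw, na.rm = TRUE))
  if (!is.finite(mx) || mx <= 0) stop("no positive score to scale against")
  setNames(raw / mx, species)
}

#' All production-function scores for a community
#'
#' Computes D, B, P, C and one `P_<family>` column per requested plant
#' family for every species in the trait table.
#'
#' @param traits a [trait_table()].
#' @param families plant families for per-family pollination scores
#'   (default: all `X_` columns present).
#' @param top_n passed to [cultural_index()].
#' @return data.frame of class `function_scores`, one row per species.
#' @export
function_scores <- function(traits, families = trait_families(traits),
                            top_n = 18L) {
  D <- density_index(traits)
  out <- data.frame(species = traits$species, D = unname(D),
                    stringsAsFactors = FALSE)
  if ("L" %in% colnames(traits)) out$B <- unname(biomass_index(traits, D))
  if ("M" %in% colnames(traits)) out$P <- unname(pollination_index(traits, D))
  if ("Y" %in% colnames(traits)) {
    out$C <- unname(cultural_index(traits, top_n = top_n))
  }
  for (fam in families) {
    out[[paste0("P_", fam)]] <-
      unname(family_pollination_index(traits, fam, D))
  }
  class(out) <- c("function_scores", "data.frame")
  out
}

#' Function-difference distance matrix
#'
#' Scales one function-score vector to zero mean and unit variance over the
#' species with a defined score, then fills a matrix with the absolute
#' pairwise differences of the z-scores (for a single score this equals the
#' Euclidean distance between species). Species with a missing score are
#' excluded listwise; the exclusion list is attached as attribute
#' `"excluded"`.
#'
#' @param scores named numeric vector of one function score (names =
#'   species); `NA` entries are dropped.
#' @return symmetric matrix of class `function_distance` over the species
#'   with defined scores, canonical order.
#' @export
function_distance <- function(scores) {
  if (is.null(names(scores))) stop("scores must be named by species")
  keep <- !is.na(scores)
  excluded <- sort(names(scores)[!keep])
  s <- scores[keep]
  if (length(s) < 3L) stop("fewer than 3 species with defined scores")
  if (sd(s) == 0) stop("zero variance in scores; distance undefined")
  z <- (s - mean(s)) / sd(s)
  f <- abs(outer(z, z, "-"))
  ord <- order(names(z))
  f <- f[ord, ord]
  attr(f, "excluded") <- excluded
  class(f) <- c("function_distance", class(f))
  f
}
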