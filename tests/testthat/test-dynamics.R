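make_ab <- function(vals, years = NULL) {
  n <- nrow(vals)
  if (is.null(years)) years <- 2000L + seq_len(ncol(vals)) - 1L
  abundance_matrix(vals, sprintf("Taxon t%02d", seq_len(n)), years)
}

test_that("standardization centers and scales each species, and is idempotent", {
  ab <- make_ab(rbind(c(1, 2, 3), c(10, 30, 20)))
  st <- standardize_abundance(ab)
  expect_equal(rowMeans(st$values), c(0, 0), ignore_attr = TRUE)
  expect_equal(apply(st$values, 1, sd), c(1, 1), ignore_attr = TRUE)
  again <- standardize_abundance(st)
  expect_equal(again$values, st$values, tolerance = 1e-12)
})

test_that("constant series are excluded with a warning naming the species", {
  ab <- make_ab(rbind(c(1, 2, 3), c(5, 5, 5), c(2, 1, 4)))
  expect_warning(st <- standardize_abundance(ab), "Taxon t02")
  expect_equal(st$species, c("Taxon t01", "Taxon t03"))
})

test_that("interannual changes difference consecutive years and propagate missingness", {
  ab <- make_ab(rbind(c(0, 0.5, 0.2), c(1, 0, 1)))
  ch <- interannual_changes(ab)
  expect_equal(ch$values[1, ], c(0.5, -0.3), ignore_attr = TRUE)
  expect_equal(ch$change_years, 2001:2002)

  vals <- matrix(rnorm(2 * 8), 2)
  vals[1, 5] <- NA                       # year 1980 missing
  ab <- make_ab(vals, years = 1976:1983)
  ch <- interannual_changes(ab)
  expect_true(all(is.na(ch$values[1, c("1980", "1981")])))
  expect_false(anyNA(ch$values[1, c("1977", "1978", "1979", "1982", "1983")]))
})

test_that("a 1976-2014 matrix yields 38 change columns labelled 1977-2014", {
  set.seed(4)
  ab <- make_ab(matrix(rnorm(5 * 39), 5), years = 1976:2014)
  ch <- interannual_changes(ab)
  expect_equal(length(ch$change_years), 38L)
  expect_equal(range(ch$change_years), c(1977L, 2014L))
})

test_that("complete-pairs correlation matches hand-computed overlap and full-sample oracle", {
  # duplicated and negated series
  base <- c(0.3, -1, 0.5, 2, -0.2, 0.9, -1.2, 0.1, 0.6, -0.4)
  ab <- make_ab(rbind(base, base, -base))
  cc <- change_correlation(interannual_changes(ab), min_pairs = 3)
  expect_equal(cc$r[1, 2], 1)
  expect_equal(cc$r[1, 3], -1)

  # interleaved missingness: brute-force Pearson over the explicit overlap
  set.seed(11)
  vals <- matrix(rnorm(2 * 20), 2)
  vals[1, c(3, 7, 15)] <- NA
  vals[2, c(4, 7, 18)] <- NA
  ab <- make_ab(vals)
  ch <- interannual_changes(ab)
  cc <- change_correlation(ch, min_pairs = 3)
  both <- !is.na(ch$values[1, ]) & !is.na(ch$values[2, ])
  a <- ch$values[1, both]; b <- ch$values[2, both]
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(cc$r[1, 2], oracle, tolerance = 1e-12)
  expect_equal(cc$n_pairs[1, 2], sum(both))

  # no missing data: equals the textbook full-sample Pearson matrix
  set.seed(12)
  vals <- matrix(rnorm(6 * 25), 6)
  ab <- make_ab(vals)
  ch <- interannual_changes(ab)
  cc <- change_correlation(ch, min_pairs = 3)
  expect_equal(cc$r, cor(t(ch$values)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("pairs below min_pairs are flagged, not fabricated", {
  set.seed(13)
  vals <- matrix(rnorm(3 * 12), 3)
  vals[1, 5:12] <- NA                     # only 4 shared years with others
  ab <- make_ab(vals)
  cc <- change_correlation(interannual_changes(ab), min_pairs = 10)
  expect_true(is.na(cc$r[1, 2]) && is.na(cc$r[1, 3]))
  expect_false(is.na(cc$r[2, 3]))
  expect_error(dynamics_distance(ab, min_pairs = 10), "complete observations")
})

test_that("distance transform is the affine map d = 1 - r with range [0, 2]", {
  r <- matrix(c(1, 1, 0, -1,
                1, 1, 0.81, 0,
                0, 0.81, 1, 0,
                -1, 0, 0, 1), 4, 4)
  d <- to_distance(r)
  expect_equal(d[1, 2], 0)
  expect_equal(d[1, 3], 1)
  expect_equal(d[1, 4], 2)
  expect_equal(d[2, 3], 1 - 0.81)
  expect_equal(diag(d), rep(0, 4))

  set.seed(14)
  for (i in 1:20) {
    r <- cor(matrix(rnorm(50 * 8), 50))
    d <- to_distance(r)
    expect_true(all(d >= 0 & d <= 2))
    # strictly decreasing affine bijection
    expect_equal(unclass(d), 1 - r, ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
  expect_error(to_distance(matrix(c(0, 1.5, 1.5, 0), 2)), "outside")
})

test_that("within-guild dynamics distances fall below between-guild distances", {
  closer <- 0L
  for (s in 1:10) {
    cfg <- community_config(n_species = 20, n_guilds = 4,
                            within_guild_rho = 0.6, n_years = 60,
                            missing_fraction = 0, seed = 100 + s)
    sim <- simulate_changes(cfg)
    d <- to_distance(cor(t(sim$changes)))
    g <- sim$truth$guild_of[rownames(d)]
    same <- outer(g, g, "==") & lower.tri(d)
    diff <- outer(g, g, "!=") & lower.tri(d)
    closer <- closer + (mean(d[same]) < mean(d[diff]))
  }
  expect_equal(closer, 10L)
})
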