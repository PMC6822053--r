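test_that("config validation rejects impossible communities", {
  expect_error(community_config(n_species = 2, n_guilds = 5))
  expect_error(community_config(within_guild_rho = 1.2))
  expect_error(community_config(density_dependence_phi = 1))
  expect_error(community_config(n_years = 2))
})

test_that("perfect within-guild coupling gives identical change series", {
  cfg <- community_config(n_species = 4, n_guilds = 2,
                          within_guild_rho = 1, n_years = 20,
                          missing_fraction = 0, seed = 61)
  sim <- simulate_changes(cfg)
  g <- sim$truth$guild_of
  same <- which(g == g[1])
  expect_equal(cor(sim$changes[same[1], ], sim$changes[same[2], ]), 1)
})

test_that("independent species decorrelate as the series lengthens", {
  cfg <- community_config(n_species = 6, n_guilds = 2,
                          within_guild_rho = 0, n_years = 2001,
                          missing_fraction = 0, seed = 62)
  sim <- simulate_changes(cfg)
  r <- cor(t(sim$changes))
  expect_lt(mean(abs(r[lower.tri(r)])), 0.06)
})

test_that("sample within-guild correlation concentrates around rho", {
  # Monte-Carlo check against the closed-form expectation rho = 0.8
  hits <- 0L
  for (s in 1:200) {
    cfg <- community_config(n_species = 2, n_guilds = 1,
                            within_guild_rho = 0.8, n_years = 401,
                            missing_fraction = 0, seed = s)
    ch <- simulate_changes(cfg)$changes
    hits <- hits + (abs(cor(ch[1, ], ch[2, ]) - 0.8) <= 0.05)
  }
  expect_gte(hits, 190L)      # >= 95% of 200 seeds
})

test_that("AR(1) integration inverts to the original changes", {
  ch <- rbind(c(0.5, -0.3), c(1, -1))
  rownames(ch) <- c("A a", "B b"); colnames(ch) <- 2001:2002
  ab <- integrate_to_abundance(ch, phi = 0, start_year = 2000)
  expect_equal(ab$values[1, ], c(0, 0.5, 0.2), ignore_attr = TRUE)
  back <- interannual_changes(ab)
  expect_equal(back$values, ch, ignore_attr = TRUE)

  zeros <- matrix(0, 2, 5, dimnames = list(c("A a", "B b"), 2001:2005))
  ab0 <- integrate_to_abundance(zeros, phi = 0.5)
  expect_true(all(ab0$values == 0))
})

test_that("missingness is applied at the requested rate, sparing early years", {
  cfg <- community_config(n_species = 30, n_years = 40,
                          missing_fraction = 0, seed = 63)
  ab <- integrate_to_abundance(simulate_changes(cfg)$changes, 0.2)
  miss <- apply_missingness(ab, 0.1, seed = 64)
  expect_false(anyNA(miss$values[, 1:2]))
  eligible <- length(miss$species) * (length(miss$years) - 2)
  rate <- sum(is.na(miss$values)) / eligible
  expect_lt(abs(rate - 0.1), 0.03)
})

test_that("tree sets are exact copies without noise and converge with it", {
  cfg <- community_config(n_species = 8,
                          heritability_mode = "brownian_loadings",
                          seed = 65)
  tr <- simulate_changes(cfg)$truth$true_tree
  same <- simulate_trees(tr, 5, tree_noise = 0, seed = 1)
  expect_length(same, 5L)
  for (t2 in same) expect_equal(t2$edge.length, tr$edge.length)
  one <- simulate_trees(tr, 1, tree_noise = 0.5, seed = 1)
  expect_length(one, 1L)
})

test_that("brownian loadings are unit rows and give phylogenetic signal in dynamics", {
  trend <- numeric(10)
  for (s in 1:10) {
    cfg <- community_config(n_species = 20, n_guilds = 4,
                            within_guild_rho = 0.8, n_years = 200,
                            heritability_mode = "brownian_loadings",
                            missing_fraction = 0, seed = 600 + s)
    sim <- simulate_changes(cfg)
    expect_equal(rowSums(sim$truth$loadings^2), rep(1, 20),
                 ignore_attr = TRUE, tolerance = 1e-12)
    pd <- patristic_matrix(sim$truth$true_tree)
    sp <- rownames(pd)
    r <- cor(t(sim$changes))[sp, sp]
    lt <- lower.tri(pd)
    trend[s] <- cor(pd[lt], r[lt])
  }
  # closer species have stochastically larger change-correlations
  expect_lt(mean(trend), -0.1)
  expect_gt(mean(trend < 0), 0.8)
})

test_that("generators are deterministic in the seed and sensitive to it", {
  cfg <- community_config(n_species = 10, n_years = 15, seed = 66)
  s1 <- simulate_community(cfg)
  s2 <- simulate_community(cfg)
  expect_identical(s1$abundance$values, s2$abundance$values)
  expect_identical(s1$traits, s2$traits)
  cfg2 <- community_config(n_species = 10, n_years = 15, seed = 67)
  s3 <- simulate_community(cfg2)
  expect_false(identical(s1$abundance$values, s3$abundance$values))
})

test_that("trait scenarios place survey counts as designed", {
  cfg <- community_config(n_species = 54, n_guilds = 4, seed = 68)
  sim <- simulate_changes(cfg)
  disp <- simulate_traits(sim$truth, scenario = "dispersed", seed = 69)
  expect_equal(sum(!is.na(disp$Y)), 18L)
  clus <- simulate_traits(sim$truth, scenario = "clustered", seed = 69)
  expect_equal(sum(!is.na(clus$Y)), 18L)
  g1 <- names(sim$truth$guild_of)[sim$truth$guild_of == 1]
  expect_true(all(g1 %in% clus$species[!is.na(clus$Y)]))
})

test_that("clustered traits induce positive dynamics-function association", {
  r_clus <- numeric(8); p_disp <- numeric(8)
  for (s in 1:8) {
    cfg <- community_config(n_species = 40, n_guilds = 4,
                            within_guild_rho = 0.8, n_years = 100,
                            missing_fraction = 0, seed = 700 + s)
    sim <- simulate_changes(cfg)
    d <- to_distance(cor(t(sim$changes)))
    clus <- simulate_traits(sim$truth, scenario = "clustered",
                            seed = 800 + s)
    fd <- function_distance(density_index(clus))
    al <- align_matrices(d, fd, quiet = TRUE)
    r_clus[s] <- mantel_statistic(al$m1, al$m2)
    disp <- simulate_traits(sim$truth, scenario = "dispersed",
                            seed = 800 + s)
    fdd <- function_distance(density_index(disp))
    ald <- align_matrices(d, fdd, quiet = TRUE)
    p_disp[s] <- mantel_test(ald$m1, ald$m2, n_perm = 199, n_boot = 0,
                             seed = s)$p
  }
  expect_gt(mean(r_clus), 0)
  expect_gt(mean(r_clus > 0), 0.7)
  # dispersed scenario behaves like a null
  expect_gt(mean(p_disp), 0.15)
})
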