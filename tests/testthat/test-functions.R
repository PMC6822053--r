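tt <- function(...) trait_table(data.frame(..., stringsAsFactors = FALSE))

test_that("density index scales O*A to a unit maximum", {
  tr <- tt(species = c("Aglais io", "Pieris napi"), O = c(10, 5),
           A = c(2, 2))
  expect_equal(unname(density_index(tr)), c(1, 0.5))
  single <- tt(species = "Aglais io", O = 3, A = 7)
  expect_equal(unname(density_index(single)), 1)
  expect_error(density_index(tt(species = c("A a", "B b"), O = c(0, 0),
                                A = c(1, 1))), "zero")
})

test_that("biomass index combines density and larval length, missing L propagates", {
  tr <- tt(species = c("Aglais io", "Pieris napi", "Pieris rapae"),
           O = c(10, 5, 4), A = c(2, 2, 1), L = c(10, 20, NA))
  B <- biomass_index(tr)
  expect_equal(unname(B), c(1, 1, NA))      # D = (1, .5, .2); D*L ties at 10
  tr2 <- tt(species = c("Aglais io", "Pieris napi"), O = c(10, 5),
            A = c(2, 2), L = c(15, 15))
  D <- density_index(tr2)
  expect_equal(unname(biomass_index(tr2)), unname(D / max(D)))
})

test_that("pollination indices use mobility, with true zeros for non-visitors", {
  tr <- tt(species = c("Aglais io", "Pieris napi"), O = c(10, 10),
           A = c(1, 1), M = c(2, 1), X_Rosaceae = c(1L, 1L))
  expect_equal(unname(pollination_index(tr)), c(1, 0.5))
  expect_equal(unname(family_pollination_index(tr, "Rosaceae")), c(1, 0.5))

  tr2 <- tt(species = c("Aglais io", "Pieris napi", "Pieris rapae"),
            O = c(10, 10, 10), A = c(1, 1, 1), M = c(2, 1, 3),
            X_Rosaceae = c(0L, 1L, 1L))
  px <- family_pollination_index(tr2, "Rosaceae")
  expect_equal(px[["Aglais io"]], 0)
  expect_equal(unname(px), c(0, 1 / 3, 1))

  tr3 <- tt(species = c("A a", "B b"), O = c(1, 1), A = c(1, 1),
            M = c(1, 1), X_Rosaceae = c(0L, 0L))
  expect_error(family_pollination_index(tr3, "Rosaceae"), "undefined")
})

test_that("cultural index scores only surveyed species, zero otherwise", {
  tr <- tt(species = c("Aglais io", "Pieris napi", "Pieris rapae"),
           O = c(1, 1, 1), A = c(1, 1, 1), Y = c(100, 50, NA))
  C <- suppressMessages(cultural_index(tr))
  expect_equal(unname(C), c(1, 0.5, 0))
  expect_equal(names(which.max(C)), "Aglais io")
})

test_that("published fixture: 8 Brassicaceae and 9 Caryophyllaceae visitors score above zero", {
  t2 <- read_function_score_table()
  expect_equal(sum(t2$P_Brassicaceae > 0, na.rm = TRUE), 8L)
  expect_equal(sum(t2$P_Caryophyllaceae > 0, na.rm = TRUE), 9L)
})

test_that("scores are homogeneous of degree zero in each raw input", {
  tr <- trait_table(tiny_trait_df())
  base <- function_scores(tr, top_n = 3)
  sc <- tr
  sc$O <- sc$O * 7.3; sc$L <- sc$L * 0.2; sc$M <- sc$M * 12
  sc$Y <- sc$Y * 3
  rescaled <- function_scores(sc, top_n = 3)
  expect_equal(rescaled, base, tolerance = 1e-12)
})

test_that("function-difference matrix is |z_i - z_j| over defined species", {
  s <- setNames(c(0, 1, 2), c("A a", "B b", "C c"))
  f <- function_distance(s)
  expect_equal(f["A a", "C c"], 2)
  expect_equal(f["A a", "B b"], 1)
  expect_equal(diag(f), rep(0, 3), ignore_attr = TRUE)

  s2 <- setNames(c(0.4, NA, 1, 2, NA), sprintf("Taxon t%02d", 1:5))
  f2 <- function_distance(s2)
  expect_equal(dim(f2), c(3L, 3L))
  expect_equal(attr(f2, "excluded"), c("Taxon t02", "Taxon t05"))

  expect_error(function_distance(setNames(rep(1, 4), letters[1:4])),
               "variance")

  # translation/scale invariance of the raw scores
  set.seed(41)
  raw <- setNames(runif(8), sprintf("Taxon t%02d", 1:8))
  expect_equal(unclass(function_distance(raw)),
               unclass(function_distance(5 + 3 * raw)), tolerance = 1e-12)
})

test_that("the fixture biomass column yields a 46 x 46 distance matrix", {
  t2 <- read_function_score_table()
  f <- function_distance(setNames(t2$B, t2$species))
  expect_equal(dim(f), c(46L, 46L))
  expect_length(attr(f, "excluded"), 8L)
})

test_that("every defined score lies in [0, 1] with maximum exactly 1", {
  cfg <- community_config(n_species = 30, n_guilds = 3, seed = 8)
  sim <- simulate_changes(cfg)
  traits <- simulate_traits(sim$truth, seed = 88)
  sc <- function_scores(traits)
  for (col in setdiff(colnames(sc), "species")) {
    v <- sc[[col]]
    expect_true(all(v >= 0 & v <= 1, na.rm = TRUE), label = col)
    expect_equal(max(v, na.rm = TRUE), 1, label = col)
  }
})
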