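#' Configuration for a synthetic community
#'
#' Bundles all parameters of the synthetic-community generator. Defaults
#' mirror the study system the package targets: 54 species monitored for 39
#' consecutive years with occasional missing species-year indices, a set of
#' 1,000 candidate phylogenies, and interannual dynamics driven by shared
#' environmental drivers that induce within-guild synchrony.
#'
#' @param n_species number of species (default 54).
#' @param n_years number of calendar years (default 39, i.e. 38 interannual
#'   changes).
#' @param n_guilds number of response guilds / latent drivers (default 4).
#' @param within_guild_rho expected Pearson correlation of interannual
#'   changes for two species in the same guild, in \[0, 1\] (default 0.6).
#' @param density_dependence_phi AR(1) coefficient for integrating changes
#'   into abundance, in \[0, 1) (default 0.2).
#' @param missing_fraction fraction of species-year cells set missing
#'   completely at random (default 0.05); a species' first two years are
#'   never removed.
#' @param heritability_mode `"guild_blocks"` (block-structured correlation,
#'   no phylogenetic signal in dynamics) or `"brownian_loadings"` (driver
#'   loadings evolve by Brownian motion along the true tree, so related
#'   species respond alike).
#' @param n_trees number of trees in the simulated tree set (default 1000).
#' @param tree_noise lognormal sd of multiplicative branch-length
#'   perturbations across trees (default 0.2; 0 = identical trees).
#' @param start_year first calendar year (default 1976).
#' @param seed integer seed; every generator output is a deterministic
#'   function of the config including this seed.
#' @return validated list of class `community_config`.
#' @export
community_config <- function(n_species = 54L, n_years = 39L, n_guilds = 4L,
                             within_guild_rho = 0.6,
                             density_dependence_phi = 0.2,
                             missing_fraction = 0.05,
                             heritability_mode = c("guild_blocks",
                                                   "brownian_loadings"),
                             n_trees = 1000L, tree_noise = 0.2,
                             start_year = 1976L, seed = 1L) {
  heritability_mode <- match.arg(heritability_mode)
  stopifnot(n_species >= n_guilds, n_guilds >= 1L, n_years >= 3L,
            within_guild_rho >= 0, within_guild_rho <= 1,
            density_dependence_phi >= 0, density_dependence_phi < 1,
            missing_fraction >= 0, missing_fraction < 1,
            n_trees >= 1L, tree_noise >= 0)
  structure(list(n_species = as.integer(n_species),
                 n_years = as.integer(n_years),
                 n_guilds = as.integer(n_guilds),
                 within_guild_rho = within_guild_rho,
                 density_dependence_phi = density_dependence_phi,
                 missing_fraction = missing_fraction,
                 heritability_mode = heritability_mode,
                 n_trees = as.integer(n_trees),
                 tree_noise = tree_noise,
                 start_year = as.integer(start_year),
                 seed = as.integer(seed)),
            class = "community_config")
}

synthetic_species_names <- function(n) {
  sprintf("Species sp%03d", seq_len(n))
}

#' Simulate guild-structured interannual changes
#'
#' Each guild g has a latent yearly environmental driver e_g(t), iid
#' standard normal. In `guild_blocks` mode species i in guild g changes by
#' `sqrt(rho) * e_g(t) + sqrt(1 - rho) * eps_i(t)` with iid standard-normal
#' idiosyncratic noise, so the expected change-correlation is exactly `rho`
#' within a guild and 0 between guilds. In `brownian_loadings` mode each
#' species carries a unit-norm loading vector over the K = `n_guilds`
#' drivers, evolved by Brownian motion along a simulated pure-birth tree
#' (rescaled to height 1), and changes by
#' `sqrt(rho) * l_i . e(t) + sqrt(1 - rho) * eps_i(t)`; the expected
#' correlation of two species is then `rho` times the cosine of their
#' loading vectors, giving closely related species more similar dynamics.
#'
#' @param config a [community_config()].
#' @return list with `changes` (species x (n_years - 1) matrix of
#'   interannual changes, variance 1) and `truth`, a `ground_truth` list
#'   with `guild_of`, `loadings` and (in brownian mode) `true_tree`.
#' @export
simulate_changes <- function(config) {
  stopifnot(inherits(config, "community_config"))
  set.seed(config$seed)
  n <- config$n_species
  tt <- config$n_years - 1L
  g <- config$n_guilds
  rho <- config$within_guild_rho
  species <- synthetic_species_names(n)
  drivers <- matrix(rnorm(g * tt), nrow = g)

  if (config$heritability_mode == "guild_blocks") {
    guild_of <- rep(seq_len(g), length.out = n)
    guild_of <- sort(guild_of)
    loadings <- matrix(0, n, g)
    loadings[cbind(seq_len(n), guild_of)] <- 1
    true_tree <- NULL
  } else {
    true_tree <- simulate_true_tree(n, species)
    bm <- vapply(seq_len(g), function(k) {
      ape::rTraitCont(true_tree, model = "BM", sigma = 1)
    }, numeric(n))
    bm <- bm[species, , drop = FALSE]
    norms <- sqrt(rowSums(bm^2))
    norms[norms == 0] <- 1
    loadings <- bm / norms
    pd <- patristic_matrix(true_tree)[species, species]
    guild_of <- relabel_first_appearance(
      cutree(hclust(as.dist(pd), method = "average"), k = g))
  }

  signal <- loadings %*% drivers
  eps <- matrix(rnorm(n * tt), nrow = n)
  changes <- sqrt(rho) * signal + sqrt(1 - rho) * eps
  rownames(changes) <- species
  colnames(changes) <- config$start_year + seq_len(tt)
  rownames(loadings) <- species
  truth <- structure(list(guild_of = setNames(guild_of, species),
                          loadings = loadings, true_tree = true_tree),
                     class = "ground_truth")
  list(changes = changes, truth = truth)
}

# pure-birth tree with unit birth rate, rescaled to height 1 so branch
# lengths are comparable across replicates
simulate_true_tree <- function(n, species) {
  tr <- ape::rphylo(n, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- species[as.integer(sub("^t", "", tr$tip.label))]
  tr
}

#' Integrate interannual changes into an abundance series
#'
#' Builds a standardizable log abundance index by the mean-reverting
#' recursion `x_t = (1 - phi) * x_(t-1) + delta_t` with `x_0 = 0`. `phi`
#' is the strength of density dependence: `phi = 0` gives a random walk
#' (plain cumulative sums, whose first differences recover the changes
#' exactly), larger `phi` pulls the log index back toward its mean so the
#' realized interannual changes recover `delta` only up to the AR
#' filtering.
#'
#' @param changes species x time matrix of interannual changes (rows named
#'   by species, columns by year of the change).
#' @param phi density-dependence strength in \[0, 1).
#' @param start_year calendar year of the initial state `x_0`.
#' @return an [abundance_matrix()] with `ncol(changes) + 1` years.
#' @export
integrate_to_abundance <- function(changes, phi = 0, start_year = 1976L) {
  stopifnot(phi >= 0, phi < 1)
  n <- nrow(changes); tt <- ncol(changes)
  x <- matrix(0, n, tt + 1L)
  for (t in seq_len(tt)) x[, t + 1L] <- (1 - phi) * x[, t] + changes[, t]
  abundance_matrix(x, rownames(changes),
                   start_year + 0:tt)
}

#' Remove species-year cells completely at random
#'
#' Sets cells missing at rate `fraction`, never touching a species' first
#' two years so that every series keeps at least two observations and the
#' abundance matrix stays analyzable.
#'
#' @param x an [abundance_matrix()].
#' @param fraction missingness rate in \[0, 1).
#' @param seed optional integer seed.
#' @return an [abundance_matrix()] with `NA` cells.
#' @export
apply_missingness <- function(x, fraction, seed = NULL) {
  stopifnot(inherits(x, "abundance_matrix"), fraction >= 0, fraction < 1)
  if (fraction == 0) return(x)
  if (!is.null(seed)) set.seed(seed)
  vals <- x$values
  eligible <- which(col(vals) > 2L)
  drop <- eligible[runif(length(eligible)) < fraction]
  vals[drop] <- NA_real_
  abundance_matrix(vals, x$species, x$years)
}

#' Simulate a set of trees around a true phylogeny
#'
#' Emulates a posterior sample of phylogenies: each output tree is the true
#' tree with every branch length multiplied by an independent lognormal
#' factor with mean 1 (meanlog `-tree_noise^2/2`, sdlog `tree_noise`), so
#' the average patristic distance matrix converges to the true tree's as
#' the number of trees grows. `tree_noise = 0` returns identical copies.
#'
#' @param true_tree a `phylo` object.
#' @param n_trees number of trees.
#' @param tree_noise lognormal sdlog of branch perturbations (>= 0).
#' @param seed optional integer seed.
#' @return a `multiPhylo` of `n_trees` trees.
#' @export
simulate_trees <- function(true_tree, n_trees, tree_noise = 0.2,
                           seed = NULL) {
  stopifnot(inherits(true_tree, "phylo"), n_trees >= 1L, tree_noise >= 0)
  if (!is.null(seed)) set.seed(seed)
  ne <- length(true_tree$edge.length)
  trees <- lapply(seq_len(n_trees), function(i) {
    tr <- true_tree
    if (tree_noise > 0) {
      tr$edge.length <- tr$edge.length *
        exp(rnorm(ne, mean = -tree_noise^2 / 2, sd = tree_noise))
    }
    tr
  })
  structure(trees, class = "multiPhylo")
}

#' Simulate a species trait table
#'
#' Draws trait values on the scales seen in national butterfly datasets:
#' occupancy `O` and survey abundance `A` as positive lognormal-shaped
#' integers, larval length `L` (mm) and mobility `M` lognormal with a
#' fraction of species missing `L` or `M`, binary visitation flags per
#' plant family, and public-survey counts `Y` for exactly `top_n` species.
#' Two scenarios control where high function scores sit relative to the
#' true guilds: `"clustered"` concentrates high density and all `Y` scores
#' in guild 1 (creating a positive association between function differences
#' and dynamics distances), `"dispersed"` spreads them at random (a null).
#'
#' @param truth `ground_truth` from [simulate_changes()].
#' @param scenario `"dispersed"` (default) or `"clustered"`.
#' @param families character vector of plant family names (default two
#'   families).
#' @param top_n number of species given a public-survey count `Y`
#'   (default 18, capped at the species count).
#' @param missing_L_fraction fraction of species with unknown larval length
#'   (default 0.15, emulating published trait coverage).
#' @param visit_prob per-family probability that a species visits it
#'   (default 0.16).
#' @param seed optional integer seed.
#' @return a [trait_table()].
#' @export
simulate_traits <- function(truth, scenario = c("dispersed", "clustered"),
                            families = c("Brassicaceae", "Caryophyllaceae"),
                            top_n = 18L, missing_L_fraction = 0.15,
                            visit_prob = 0.16, seed = NULL) {
  scenario <- match.arg(scenario)
  if (!is.null(seed)) set.seed(seed)
  species <- names(truth$guild_of)
  n <- length(species)
  top_n <- min(as.integer(top_n), n)
  O <- pmax(1, round(exp(rnorm(n, 5, 1))))
  A <- pmax(1, round(exp(rnorm(n, 2, 0.8))))
  L <- exp(rnorm(n, log(25), 0.4))
  M <- exp(rnorm(n, 0, 0.5))
  L[sample.int(n, round(missing_L_fraction * n))] <- NA_real_
  in_g1 <- truth$guild_of == min(truth$guild_of)
  if (scenario == "clustered") {
    O[in_g1] <- O[in_g1] * 25
    pool <- c(which(in_g1), sample(which(!in_g1)))
    top_idx <- head(pool, top_n)
  } else {
    top_idx <- sample.int(n, top_n)
  }
  Y <- rep(NA_real_, n)
  Y[top_idx] <- exp(rnorm(top_n, 4, 1))
  df <- data.frame(species = species, O = O, A = A, L = L, M = M, Y = Y,
                   stringsAsFactors = FALSE)
  for (fam in families) {
    x <- rbinom(n, 1L, visit_prob)
    if (sum(x) == 0) x[sample.int(n, 1L)] <- 1L  # keep P_x defined
    df[[paste0("X_", fam)]] <- x
  }
  trait_table(df)
}

#' Simulate a complete community: abundance, trees, traits, ground truth
#'
#' One call producing aligned inputs for the full pipeline. Sub-seeds for
#' each stage are derived deterministically from `config$seed`.
#'
#' @param config a [community_config()].
#' @param scenario trait scenario, see [simulate_traits()].
#' @return list with `abundance` ([abundance_matrix()] after AR(1)
#'   integration and missingness), `changes` (noise-free change matrix),
#'   `trees` (`multiPhylo`; only when a true tree exists, i.e. brownian
#'   mode), `traits` ([trait_table()]) and `truth`.
#' @export
simulate_community <- function(config, scenario = "dispersed") {
  stopifnot(inherits(config, "community_config"))
  sim <- simulate_changes(config)
  ab <- integrate_to_abundance(sim$changes, config$density_dependence_phi,
                               config$start_year)
  ab <- apply_missingness(ab, config$missing_fraction,
                          seed = config$seed + 1L)
  trees <- NULL
  if (!is.null(sim$truth$true_tree)) {
    trees <- simulate_trees(sim$truth$true_tree, config$n_trees,
                            config$tree_noise, seed = config$seed + 2L)
  }
  traits <- simulate_traits(sim$truth, scenario = scenario,
                            seed = config$seed + 3L)
  list(abundance = ab, changes = sim$changes, trees = trees,
       traits = traits, truth = sim$truth)
}

#' Write a simulated community to disk
#'
#' Writes the pipeline's three input files (abundance CSV, trait CSV,
#' Newick tree set) plus a ground-truth JSON with guild labels and
#' loadings.
#'
#' @param sim output of [simulate_community()].
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_community <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(abundance = file.path(dir, "abundance.csv"),
             traits = file.path(dir, "traits.csv"),
             truth = file.path(dir, "ground_truth.json"))
  write_abundance(sim$abundance, paths[["abundance"]])
  write_trait_table(sim$traits, paths[["traits"]])
  if (!is.null(sim$trees)) {
    paths[["trees"]] <- file.path(dir, "trees.nwk")
    tr <- sim$trees
    for (i in seq_along(tr)) {
      tr[[i]]$tip.label <- gsub(" ", "_", tr[[i]]$tip.label)
    }
    ape::write.tree(tr, paths[["trees"]])
  }
  jsonlite::write_json(
    list(guild_of = as.list(sim$truth$guild_of),
         loadings = sim$truth$loadings),
    paths[["truth"]], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
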