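#' Assemble and validate a pipeline run configuration
#'
#' @param abundance path to the abundance index CSV (see
#'   [read_abundance()]). Required.
#' @param traits path to the trait CSV ([read_trait_table()]), or `NULL` to
#'   skip the production-function comparisons.
#' @param trees path to a Newick tree-set file ([read_tree_set()]), or
#'   `NULL` to skip the phylogenetic comparison.
#' @param linkage_method agglomeration method for [build_linkage()].
#' @param cut_k integer vector of guild-count resolutions for
#'   [cut_dendrogram()] (default `c(2, 4, 6, 10)`, the four published
#'   resolutions).
#' @param families plant families for per-family pollination scores;
#'   `NULL` = all families in the trait table.
#' @param n_perm,n_boot Mantel permutations and bootstrap replicates.
#' @param min_pairs minimum complete pairs per correlation.
#' @param top_n expected number of species with a cultural-survey count.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(abundance, traits = NULL, trees = NULL,
                       linkage_method = "complete",
                       cut_k = c(2L, 4L, 6L, 10L), families = NULL,
                       n_perm = 9999L, n_boot = 500L, min_pairs = 10L,
                       top_n = 18L, seed = 1L) {
  stopifnot(is.character(abundance), length(abundance) == 1L,
            n_perm >= 99L, n_boot >= 0L, min_pairs >= 3L)
  if (!file.exists(abundance)) stop("abundance file not found: ", abundance)
  for (p in c(traits, trees)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  structure(list(abundance = abundance, traits = traits, trees = trees,
                 linkage_method = linkage_method,
                 cut_k = as.integer(cut_k), families = families,
                 n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
                 min_pairs = as.integer(min_pairs),
                 top_n = as.integer(top_n), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Report species overlap and missingness across the pipeline inputs
#'
#' Lists, before any computation, which species will be dropped at each
#' alignment step: abundance species with no tree, tree taxa with no
#' abundance series, and per-function trait gaps (missing `L` or `M`).
#'
#' @param config a [run_config()].
#' @return list with `n_abundance`, `no_tree`, `no_abundance`,
#'   `missing_L`, `missing_M`, `missingness` (fraction of missing
#'   abundance cells).
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ab <- read_abundance(config$abundance)
  out <- list(n_abundance = length(ab$species),
              missingness = mean(is.na(ab$values)),
              no_tree = character(0), no_abundance = character(0),
              missing_L = character(0), missing_M = character(0))
  if (!is.null(config$trees)) {
    taxa <- sort(read_tree_set(config$trees)[[1L]]$tip.label)
    out$no_tree <- setdiff(ab$species, taxa)
    out$no_abundance <- setdiff(taxa, ab$species)
  }
  if (!is.null(config$traits)) {
    tr <- read_trait_table(config$traits)
    if ("L" %in% colnames(tr)) out$missing_L <- tr$species[is.na(tr$L)]
    if ("M" %in% colnames(tr)) out$missing_M <- tr$species[is.na(tr$M)]
  }
  out
}

#' Run the full response-guild analysis
#'
#' End-to-end pipeline: read inputs, compute the population-dynamics
#' distance matrix, cluster species into response guilds at the configured
#' resolutions, average patristic distances over the tree set, compute
#' production-function scores and their difference matrices, and run one
#' Mantel test per comparison (phylogeny, biomass, cultural, general and
#' per-family pollination). All outputs are written to `out_dir`; two runs
#' with identical config and inputs produce byte-identical numeric output.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with `distance`, `linkage`, `guilds`, `scores`,
#'   `mantel` and the vector of written `paths`.
#' @export
run_full_analysis <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  ab <- read_abundance(config$abundance)
  say("abundance: ", length(ab$species), " species x ", length(ab$years),
      " years, ", round(100 * mean(is.na(ab$values)), 1), "% cells missing")

  dyn <- dynamics_distance(ab, min_pairs = config$min_pairs)
  d <- dyn$d
  say("dynamics distance: ", nrow(d), " species")

  hc <- build_linkage(d, method = config$linkage_method)
  guilds <- cut_dendrogram(hc, k = config$cut_k)
  say("guilds: resolutions ", paste(config$cut_k, collapse = ", "),
      " (", config$linkage_method, " linkage)")

  pairs <- list()
  if (!is.null(config$trees)) {
    trees <- read_tree_set(config$trees)
    g <- average_patristic(trees)
    al <- align_matrices(d, g, quiet = TRUE)
    say("phylogeny: ", length(trees), " trees; ", length(al$species),
        " of ", nrow(d), " species shared with dynamics matrix")
    pairs[[length(pairs) + 1L]] <- list(
      name1 = "Population dynamics", name2 = "Phylogenetic tree",
      m1 = d, m2 = g)
  }

  scores <- NULL
  if (!is.null(config$traits)) {
    traits <- read_trait_table(config$traits)
    fams <- if (is.null(config$families)) trait_families(traits) else
      config$families
    scores <- function_scores(traits, families = fams,
                              top_n = config$top_n)
    score_cols <- c(B = "Larval biomass", C = "Cultural function",
                    P = "General wildflower pollination score")
    for (col in names(score_cols)) {
      if (!col %in% colnames(scores)) next
      fd <- try(function_distance(setNames(scores[[col]], scores$species)),
                silent = TRUE)
      if (inherits(fd, "try-error")) {
        say("skipping ", score_cols[[col]], ": ",
            attr(fd, "condition")$message)
        next
      }
      if (length(attr(fd, "excluded"))) {
        say(score_cols[[col]], ": excluding ",
            length(attr(fd, "excluded")), " species with missing inputs")
      }
      pairs[[length(pairs) + 1L]] <- list(
        name1 = "Population dynamics", name2 = score_cols[[col]],
        m1 = d, m2 = fd)
    }
    for (fam in fams) {
      col <- paste0("P_", fam)
      fd <- try(function_distance(setNames(scores[[col]], scores$species)),
                silent = TRUE)
      if (inherits(fd, "try-error")) {
        say("skipping ", fam, " pollination: ",
            attr(fd, "condition")$message)
        next
      }
      pairs[[length(pairs) + 1L]] <- list(
        name1 = "Population dynamics",
        name2 = paste(fam, "pollination score"), m1 = d, m2 = fd)
    }
  }

  mantel_tab <- mantel_report(pairs, n_perm = config$n_perm,
                              n_boot = config$n_boot,
                              seed = config$seed, tail = "greater")
  say("mantel: ", nrow(mantel_tab), " comparisons, ", config$n_perm,
      " permutations, ", config$n_boot, " bootstrap replicates")

  # ---- outputs ------------------------------------------------------------
  cfg_yaml <- yaml::as.yaml(unclass(config))
  header <- c(paste0("respguild ",
                     as.character(utils::packageVersion("respguild"))),
              paste0("seed=", config$seed),
              paste0("config_hash=", fnv1a_hash(cfg_yaml)))
  paths <- write_results(mantel_tab, out_dir, guilds = guilds,
                         header = header)
  dcsv <- file.path(out_dir, "dynamics_distance.csv")
  write.csv(as.data.frame(format(unclass(d), digits = 15, trim = TRUE)),
            dcsv, quote = FALSE)
  ncsv <- file.path(out_dir, "n_pairs.csv")
  write.csv(as.data.frame(dyn$n_pairs), ncsv, quote = FALSE)
  scsv <- file.path(out_dir, "function_scores.tsv")
  if (!is.null(scores)) {
    write.table(format_num_df(scores), scsv, sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  export_linkage(hc, json_path = file.path(out_dir, "dendrogram.json"),
                 newick_path = file.path(out_dir, "dendrogram.nwk"))
  writeLines(cfg_yaml, file.path(out_dir, "config.yaml"))
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  paths <- c(paths, dcsv, ncsv, scsv,
             file.path(out_dir, c("dendrogram.json", "dendrogram.nwk",
                                  "config.yaml", "log.txt")))

  invisible(list(distance = d, n_pairs = dyn$n_pairs, linkage = hc,
                 guilds = guilds, scores = scores, mantel = mantel_tab,
                 paths = paths))
}

# deterministic polynomial hash for provenance headers (not cryptographic)
fnv1a_hash <- function(x) {
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
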