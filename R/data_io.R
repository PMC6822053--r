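#' Normalize species names to canonical binomial form
#'
#' Species labels arriving from different sources (abundance tables, trait
#' tables, Newick tip labels) are reconciled by a single canonical form:
#' underscores become spaces, runs of whitespace collapse to one space,
#' leading/trailing whitespace is stripped, and case is normalized so the
#' genus is capitalized and the rest is lower case (e.g. `"maniola_jurtina "`
#' becomes `"Maniola jurtina"`). The transform is idempotent and
#' order-preserving.
#'
#' @param x character vector of species labels.
#' @return character vector of canonical names.
#' @export
#' @examples
#' normalize_species_names(c("maniola_jurtina", "  Pieris   RAPAE "))
normalize_species_names <- function(x) {
  if (!is.character(x)) x <- as.character(x)
  out <- gsub("_", " ", x)
  out <- gsub("[[:space:]]+", " ", out)
  out <- trimws(out)
  if (any(!nzchar(out))) stop("empty species name after normalization")
  out <- tolower(out)
  substr(out, 1L, 1L) <- toupper(substr(out, 1L, 1L))
  out
}

#' Construct an abundance matrix object
#'
#' An `abundance_matrix` holds standardized (or raw) log abundance indices
#' for a set of species over consecutive calendar years, with `NA` marking
#' missing species-year cells.
#'
#' @param values numeric matrix, rows = species, columns = years; `NA` =
#'   missing.
#' @param species character vector of species names (normalized internally).
#' @param years integer vector of consecutive calendar years.
#' @return an object of class `abundance_matrix`: a list with elements
#'   `species`, `years`, `values`.
#' @export
abundance_matrix <- function(values, species, years) {
  values <- as.matrix(values)
  species <- normalize_species_names(species)
  years <- as.integer(years)
  if (length(species) != nrow(values)) {
    stop("species length does not match number of rows")
  }
  if (length(years) != ncol(values)) {
    stop("years length does not match number of columns")
  }
  if (anyDuplicated(species)) {
    stop("duplicate species: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  }
  if (length(years) < 3L) stop("need at least 3 year columns")
  if (length(species) < 2L) stop("need at least 2 species")
  if (any(diff(years) != 1L)) {
    stop("years must be consecutive; gap after ",
         years[which(diff(years) != 1L)[1L]])
  }
  n_obs <- rowSums(!is.na(values))
  if (any(n_obs < 2L)) {
    stop("species with fewer than 2 observations: ",
         paste(species[n_obs < 2L], collapse = ", "))
  }
  dimnames(values) <- list(species, years)
  structure(list(species = species, years = years, values = values),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("Abundance matrix:", length(x$species), "species x",
      length(x$years), "years (", x$years[1], "-",
      x$years[length(x$years)], "),",
      sum(is.na(x$values)), "missing cells\n")
  invisible(x)
}

#' Read an abundance index table from CSV
#'
#' Expects one species column (first) followed by one column per calendar
#' year; blank cells or `NA` denote missing species-year indices. Year
#' columns must form a consecutive run; gaps are an error.
#'
#' @param path path to a CSV file.
#' @return an [abundance_matrix()].
#' @export
read_abundance <- function(path) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                  na.strings = c("", "NA"))
  if (ncol(raw) < 4L) stop("need a species column plus at least 3 year columns")
  yrs <- suppressWarnings(as.integer(colnames(raw)[-1L]))
  if (anyNA(yrs)) {
    stop("non-year column header(s): ",
         paste(colnames(raw)[-1L][is.na(yrs)], collapse = ", "))
  }
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(apply(raw[, -1L], 2, as.numeric))) &
                   !is.na(raw[, -1L]), arr.ind = TRUE)
    stop("non-numeric abundance cell(s), e.g. row ", bad[1L, 1L])
  }
  abundance_matrix(vals, raw[[1L]], yrs)
}

#' Write an abundance matrix to CSV
#'
#' Inverse of [read_abundance()]; missing cells are written as empty
#' strings. Round-trip safe at full double precision.
#'
#' @param x an [abundance_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(x, path) {
  stopifnot(inherits(x, "abundance_matrix"))
  df <- data.frame(species = x$species,
                   format(x$values, digits = 17, trim = TRUE),
                   check.names = FALSE)
  df[df == "NA"] <- ""
  colnames(df) <- c("species", x$years)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a set of phylogenetic trees from a Newick file
#'
#' Reads one or more Newick trees (one per line), normalizes tip labels with
#' [normalize_species_names()] (underscores become spaces), and validates
#' that all trees share an identical taxon set with non-negative branch
#' lengths.
#'
#' @param path path to a Newick file.
#' @return a `multiPhylo` object (see [ape::read.tree()]).
#' @export
read_tree_set <- function(path) {
  trees <- ape::read.tree(path)
  if (is.null(trees)) stop("could not parse any Newick tree from ", path)
  if (inherits(trees, "phylo")) trees <- structure(list(trees),
                                                   class = "multiPhylo")
  trees <- validate_tree_set(trees)
  trees
}

validate_tree_set <- function(trees) {
  if (inherits(trees, "phylo")) trees <- structure(list(trees),
                                                   class = "multiPhylo")
  trees <- lapply(trees, function(tr) {
    tr$tip.label <- normalize_species_names(tr$tip.label)
    if (is.null(tr$edge.length)) stop("tree without branch lengths")
    if (any(tr$edge.length < 0)) stop("negative branch length")
    if (length(tr$tip.label) < 3L) stop("tree with fewer than 3 taxa")
    tr
  })
  ref <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    tx <- sort(trees[[i]]$tip.label)
    if (!identical(tx, ref)) {
      stop("tree ", i, " taxon set differs from tree 1: ",
           paste(c(setdiff(tx, ref), setdiff(ref, tx)), collapse = ", "))
    }
  }
  structure(trees, class = "multiPhylo")
}

#' Read a species trait table from CSV
#'
#' The table must contain a `species` column plus the mandatory trait
#' columns `O` (mean occupied 10-km squares) and `A` (mean survey
#' observations). Optional columns: `L` (larval length, mm), `M` (mobility
#' index), `Y` (mean public-survey count; absent/`NA` means not among the
#' most-recorded species), and any number of binary plant-family visitation
#' columns named `X_<Family>` (values 0/1).
#'
#' @param path path to a CSV file. Empty cells and `"NA"` are missing.
#' @return a `data.frame` of class `trait_table`, one row per species.
#' @export
read_trait_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 na.strings = c("", "NA"))
  trait_table(df)
}

#' Validate a data frame as a trait table
#'
#' @param df data.frame with columns `species`, `O`, `A` and optionally
#'   `L`, `M`, `Y` and `X_<Family>` binary columns.
#' @return the validated `trait_table`.
#' @export
trait_table <- function(df) {
  need <- c("species", "O", "A")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  df$species <- normalize_species_names(df$species)
  if (anyDuplicated(df$species)) {
    stop("duplicate species: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "))
  }
  for (col in intersect(c("O", "A", "Y"), colnames(df))) {
    v <- df[[col]]
    if (any(v < 0, na.rm = TRUE)) stop("negative values in ", col)
  }
  if (anyNA(df$O) || anyNA(df$A)) stop("O and A must be present for all species")
  xcols <- grep("^X_", colnames(df), value = TRUE)
  for (col in xcols) {
    v <- df[[col]]
    if (!all(v %in% c(0, 1), na.rm = TRUE)) {
      stop(col, " must be binary 0/1")
    }
    if (any(!nzchar(sub("^X_", "", col)))) stop("empty family name in ", col)
  }
  rownames(df) <- NULL
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Plant families present in a trait table
#' @param traits a `trait_table`.
#' @return character vector of family names (from `X_<Family>` columns).
#' @export
trait_families <- function(traits) {
  sub("^X_", "", grep("^X_", colnames(traits), value = TRUE))
}

#' Write a trait table to CSV
#' @param traits a `trait_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  out <- as.data.frame(traits)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) format(v, digits = 17, trim = TRUE))
  out[out == "NA"] <- ""
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read the published standardized function-score table
#'
#' Reads a fixture CSV of per-species standardized ecosystem-function scores
#' (larval biomass `B`, cultural function `C`, general wildflower
#' pollination `P`, and per-family pollination columns such as
#' `P_Brassicaceae`). Published tables print some small scores censored as
#' `"<0.001"` or `">0.001"`; these are stored as 0.0005 and flagged in a
#' companion logical column `<col>_censored`, so analyses can rely on their
#' sign but not their magnitude.
#'
#' @param path path to the score CSV; defaults to the copy shipped with the
#'   package (54 UK butterfly species).
#' @return a `data.frame` with a `species` column, numeric score columns and
#'   logical `*_censored` companions.
#' @export
read_function_score_table <- function(path = system.file(
    "extdata", "uk_butterfly_function_scores.csv", package = "respguild")) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 na.strings = c("", "NA"))
  df$species <- normalize_species_names(df$species)
  for (col in setdiff(colnames(df), "species")) {
    v <- trimws(as.character(df[[col]]))
    cens <- grepl("^[<>]", v)
    num <- suppressWarnings(as.numeric(sub("^[<>]", "", v)))
    num[cens] <- 0.0005
    df[[col]] <- num
    df[[paste0(col, "_censored")]] <- cens
  }
  df
}

#' Write Mantel results and guild allocations to disk
#'
#' Emits the two result tables of the analysis: a Mantel summary TSV with
#' columns `matrix1`, `matrix2`, `mantel_r`, `p_value`, `ci_lower`,
#' `ci_upper` (one row per comparison) and, if guild allocations are given,
#' a species-by-resolution TSV of guild labels. A JSON copy of the Mantel
#' results is written alongside.
#'
#' @param mantel_table data.frame as returned by [mantel_report()].
#' @param dir output directory (created if needed).
#' @param guilds optional `guild_allocation` from [cut_dendrogram()].
#' @param header optional character vector of provenance comment lines
#'   (each written prefixed with `#`).
#' @return character vector of written paths, invisibly.
#' @export
write_results <- function(mantel_table, dir, guilds = NULL, header = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  tsv <- file.path(dir, "mantel_results.tsv")
  con <- file(tsv, "w")
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(format_num_df(mantel_table), con, sep = "\t",
              row.names = FALSE, quote = FALSE)
  close(con)
  paths <- c(paths, tsv)
  js <- file.path(dir, "mantel_results.json")
  jsonlite::write_json(mantel_table, js, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  paths <- c(paths, js)
  if (!is.null(guilds)) {
    gt <- file.path(dir, "guilds.tsv")
    con <- file(gt, "w")
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    write.table(as_guild_table(guilds), con, sep = "\t",
                row.names = FALSE, quote = FALSE)
    close(con)
    paths <- c(paths, gt)
  }
  invisible(paths)
}

# fixed-width numeric formatting so identical runs yield identical bytes
format_num_df <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 15, trim = TRUE))
  df
}
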