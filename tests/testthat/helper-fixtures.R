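# small in-code fixtures shared across test files

# random symmetric matrix with iid N(0,1) lower-triangle entries, zero diag
random_symmetric <- function(n, species = NULL) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- rnorm(n * (n - 1) / 2)
  m <- m + t(m)
  if (is.null(species)) species <- sprintf("Taxon t%02d", seq_len(n))
  dimnames(m) <- list(species, species)
  m
}

# random distance-like matrix with entries in (0, 2)
random_distance <- function(n, species = NULL) {
  m <- random_symmetric(n, species)
  m[] <- 2 * stats::pnorm(m)
  diag(m) <- 0
  m
}

write_tmp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

tiny_abundance_csv <- function() {
  write_tmp_csv(c(
    "species,1990,1991,1992,1993,1994",
    "Aglais io,1.0,1.2,0.9,1.4,1.1",
    "Pieris napi,2.0,,2.2,2.5,2.1",
    "Maniola jurtina,0.5,0.6,0.4,0.8,0.7"))
}

tiny_trait_df <- function() {
  data.frame(
    species = c("Aglais io", "Pieris napi", "Maniola jurtina",
                "Pieris rapae"),
    O = c(10, 5, 20, 8), A = c(2, 4, 3, 1),
    L = c(30, 25, NA, 20), M = c(1.5, 2.0, 1.0, 0.5),
    Y = c(100, 50, NA, 80),
    X_Brassicaceae = c(1L, 1L, 0L, 1L),
    X_Caryophyllaceae = c(0L, 1L, 1L, 0L),
    stringsAsFactors = FALSE)
}
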