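# Small in-code fixtures shared across test files.

small_config <- function(seed = 11L, n_dg = 12L, n_ug = 8L,
                         populations = NULL, ...) {
  if (is.null(populations)) {
    populations <- data.frame(
      name = c("Zou", "Eastern"),
      region = c("DG", "UG"),
      n_accessions = c(n_dg, n_ug),
      stringsAsFactors = FALSE
    )
  }
  germplasm_config(seed = seed, populations = populations, ...)
}

small_collection <- function(seed = 11L, ...) {
  generate_collection(small_config(seed = seed, ...))
}

small_traits <- function(seed = 11L, ...) {
  col <- small_collection(seed = seed, ...)
  suppressWarnings(derive_traits(col$accessions, col$fruit_bulks,
                                 col$fruit_dimensions))
}

# Minimal hand-built raw tables for exact-arithmetic checks.
toy_accessions <- function(n = 1) {
  data.frame(
    accession_id = sprintf("T-%02d", seq_len(n)),
    population = "Zou", region = "DG", habitat = "farm",
    age_years = NA_real_, latitude = NA_real_, longitude = NA_real_,
    circumference_ground_cm = rep(62.8319, n),
    height_m = 3.5, crown_ns_m = 4.0, crown_ew_m = 4.0,
    stringsAsFactors = FALSE
  )
}

random_distance_matrix <- function(n, seed, dim = 3) {
  set.seed(seed)
  P <- matrix(stats::runif(n * dim), n, dim)
  D <- as.matrix(stats::dist(P))
  dimnames(D) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
  D
}
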