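# Synthetic germplasm generator.
#
# Emulates the statistical structure of an in-situ sampled perennial fruit-tree
# collection: accessions nested in populations, populations nested in two
# ecological regions (DG = Dahomey Gap, UG = Upper Guinea forest), replicate
# 10-fruit bulks per accession for mass traits, and a per-fruit dimension
# subsample. Accession-level latent trait values are multivariate normal with
# region-specific means; replicate observations are drawn around the latent
# value with within-accession variance set so that
# sigma2_among / (sigma2_among + sigma2_within) equals the configured
# repeatability target.

# Traits with directly generated latent values. EdRt is generated on the logit
# scale and back-transformed; AvSM and FrSh are derived (SM10 = FM10*(1-EdRt),
# FrSh = length/width) so their variance structure is emergent.
.latent_traits <- c("DiamGr", "PlHgt", "CrDiam", "AvFL", "AvFW", "AvFM", "EdRt")

.default_region_gaps <- c(
  DiamGr = 0, PlHgt = 0.8, CrDiam = 0,
  AvFL = 1.2, AvFW = 1.0, AvFM = 0.26, EdRt = 5.0
)

.default_correlations <- local({
  nm <- .latent_traits
  C <- diag(7)
  dimnames(C) <- list(nm, nm)
  set_r <- function(C, a, b, r) { C[a, b] <- r; C[b, a] <- r; C }
  C <- set_r(C, "DiamGr", "PlHgt", 0.45)
  C <- set_r(C, "DiamGr", "CrDiam", 0.50)
  C <- set_r(C, "PlHgt", "CrDiam", 0.62)
  C <- set_r(C, "DiamGr", "AvFL", 0.10)
  C <- set_r(C, "DiamGr", "AvFW", 0.15)
  C <- set_r(C, "DiamGr", "AvFM", 0.15)
  C <- set_r(C, "DiamGr", "EdRt", 0.10)
  C <- set_r(C, "PlHgt", "AvFL", 0.15)
  C <- set_r(C, "PlHgt", "AvFW", 0.31)
  C <- set_r(C, "PlHgt", "AvFM", 0.25)
  C <- set_r(C, "PlHgt", "EdRt", 0.15)
  C <- set_r(C, "CrDiam", "AvFL", 0.10)
  C <- set_r(C, "CrDiam", "AvFW", 0.20)
  C <- set_r(C, "CrDiam", "AvFM", 0.20)
  C <- set_r(C, "CrDiam", "EdRt", 0.10)
  C <- set_r(C, "AvFL", "AvFW", 0.49)
  C <- set_r(C, "AvFL", "AvFM", 0.55)
  C <- set_r(C, "AvFL", "EdRt", 0.30)
  C <- set_r(C, "AvFW", "AvFM", 0.83)
  C <- set_r(C, "AvFW", "EdRt", 0.45)
  C <- set_r(C, "AvFM", "EdRt", 0.63)
  C
})

# Rough population centroids (decimal degrees) along the Benin-Togo-Ghana
# coastal strip, west-to-east, for coordinate emulation only.
.population_centers <- data.frame(
  name = c("Oueme", "Zou", "Mono", "Volta", "Eastern", "Central", "Western"),
  latitude = c(6.6, 7.2, 6.7, 6.4, 6.2, 6.3, 6.0),
  longitude = c(2.5, 2.1, 1.7, 0.9, -0.4, -1.2, -2.0),
  stringsAsFactors = FALSE
)

#' Configuration for the synthetic germplasm generator
#'
#' Defaults reproduce the study conditions of the reference collection:
#' 7 populations (4 DG, 3 UG) totalling 203 accessions, trait means/SDs from
#' the published descriptive table, UG-vs-DG mean contrasts with the published
#' signs (UG taller trees, heavier/longer/wider fruits and higher edible
#' ratio; DG more oblong fruits), latent trait correlations matching the
#' published correlogram for the strongly reported pairs, and fruit-trait
#' repeatability targets from the published adjusted-repeatability table.
#'
#' @param seed master integer seed; per-population streams are derived from it
#'   by a label hash so adding a population does not perturb the others
#' @param populations data.frame with columns name, region ("DG"/"UG"),
#'   n_accessions
#' @param habitat_probs probability that an accession sits in a home garden
#'   (vs farm); scalar or named per-population vector
#' @param trait_means,trait_sds named vectors over
#'   DiamGr, PlHgt, CrDiam, AvFL, AvFW, AvFM, EdRt (EdRt on the percent
#'   scale; converted to logit internally)
#' @param region_gaps named vector of UG-minus-DG mean differences on the
#'   trait scale; the population-size-weighted mean stays at `trait_means`
#' @param trait_correlations 7x7 latent correlation matrix (EdRt entries apply
#'   to its logit); repaired to the nearest PSD matrix if slightly indefinite
#' @param repeatability_targets named vector in (0, 1] for AvFL, AvFW, AvFM,
#'   EdRt (logit scale); 1 means no within-accession noise
#' @param replicates_per_accession number of 10-fruit bulks (default 3)
#' @param fruits_per_replicate fixed at 10 (bulk size)
#' @param dimension_subsample per-fruit length/width subsample size (default 5)
#' @param with_age,with_coordinates emit optional age / coordinate columns
#' @return object of class `germplasm_config`
#' @export
germplasm_config <- function(seed = 1L,
                             populations = reference_populations(),
                             habitat_probs = 0.7,
                             trait_means = NULL,
                             trait_sds = NULL,
                             region_gaps = .default_region_gaps,
                             trait_correlations = .default_correlations,
                             repeatability_targets = c(
                               reference_repeatability()[c("AvFL", "AvFW", "AvFM")],
                               EdRt = unname(reference_repeatability()["EdRt"])
                             ),
                             replicates_per_accession = 3L,
                             fruits_per_replicate = 10L,
                             dimension_subsample = 5L,
                             with_age = TRUE,
                             with_coordinates = TRUE) {
  ref <- reference_trait_summary()
  defaults <- stats::setNames(ref$mean, ref$trait)[.latent_traits]
  default_sds <- stats::setNames(ref$sd, ref$trait)[.latent_traits]
  means <- defaults
  sds <- default_sds
  if (!is.null(trait_means)) means[names(trait_means)] <- trait_means
  if (!is.null(trait_sds)) sds[names(trait_sds)] <- trait_sds

  stopifnot(is.data.frame(populations),
            all(c("name", "region", "n_accessions") %in% names(populations)))
  if (!all(populations$region %in% c("DG", "UG"))) {
    stop("population regions must be 'DG' or 'UG'")
  }
  if (any(populations$n_accessions < 1)) stop("n_accessions must be >= 1")
  hp <- habitat_probs
  if (length(hp) == 1L) {
    hp <- stats::setNames(rep(hp, nrow(populations)), populations$name)
  }
  if (any(hp < 0 | hp > 1)) stop("habitat_probs must lie in [0, 1]")
  if (any(sds <= 0)) stop("trait SDs must be strictly positive")
  if (any(repeatability_targets <= 0 | repeatability_targets > 1)) {
    stop("repeatability targets must lie in (0, 1]")
  }
  gaps <- stats::setNames(rep(0, length(.latent_traits)), .latent_traits)
  gaps[names(region_gaps)] <- region_gaps

  C <- trait_correlations[.latent_traits, .latent_traits]
  C <- nearest_psd_correlation(C)

  structure(list(
    seed = as.integer(seed),
    populations = populations,
    habitat_probs = hp,
    trait_means = means,
    trait_sds = sds,
    region_gaps = gaps,
    trait_correlations = C,
    repeatability_targets = repeatability_targets,
    replicates_per_accession = as.integer(replicates_per_accession),
    fruits_per_replicate = as.integer(fruits_per_replicate),
    dimension_subsample = as.integer(dimension_subsample),
    with_age = isTRUE(with_age),
    with_coordinates = isTRUE(with_coordinates)
  ), class = "germplasm_config")
}

# Variance components implied by a config, on the generating scale (EdRt on
# logit). Tree traits have no replicate structure: all variance is among.
#' @keywords internal
.generating_components <- function(config) {
  means <- config$trait_means
  sds <- config$trait_sds
  p0 <- means[["EdRt"]] / 100
  sd_logit <- (sds[["EdRt"]] / 100) / (p0 * (1 - p0))
  scale_sd <- sds
  scale_sd[["EdRt"]] <- sd_logit
  R <- stats::setNames(rep(NA_real_, length(.latent_traits)), .latent_traits)
  R[names(config$repeatability_targets)] <- config$repeatability_targets
  among <- ifelse(is.na(R), scale_sd, scale_sd * sqrt(R))
  within <- ifelse(is.na(R), 0, scale_sd * sqrt(1 - R))
  data.frame(
    trait = .latent_traits,
    scale = ifelse(.latent_traits == "EdRt", "logit", "natural"),
    sigma2_among = unname(among^2),
    sigma2_within = unname(within^2),
    repeatability = unname(ifelse(is.na(R), NA_real_,
                                  among^2 / (among^2 + within^2))),
    stringsAsFactors = FALSE
  )
}

# Draw n latent rows ~ MVN(mu, diag(s) C diag(s)), resampling rows that break
# biological bounds (positive sizes and masses; EdRt is unbounded on logit).
#' @keywords internal
.draw_latents <- function(n, mu, s, chol_C) {
  p <- length(mu)
  draw <- function(m) {
    Z <- matrix(stats::rnorm(m * p), m, p) %*% chol_C
    sweep(sweep(Z, 2, s, "*"), 2, mu, "+")
  }
  X <- draw(n)
  positive <- .latent_traits != "EdRt"
  for (iter in 1:1000) {
    bad <- apply(X[, positive, drop = FALSE] <= 0, 1, any)
    if (!any(bad)) return(X)
    X[bad, ] <- draw(sum(bad))
  }
  stop("latent resampling failed to satisfy positivity bounds; ",
       "check trait means/SDs")
}

#' @keywords internal
.truncated_normal <- function(n, mean, sd, lower = 0) {
  if (all(sd == 0)) return(rep(mean, length.out = n))
  x <- stats::rnorm(n, mean, sd)
  for (iter in 1:1000) {
    bad <- x <= lower
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), if (length(mean) > 1) mean[bad] else mean,
                           if (length(sd) > 1) sd[bad] else sd)
  }
  stop("truncated-normal resampling failed; noise SD too large for the mean")
}

#' Generate a synthetic germplasm collection
#'
#' Produces raw field tables (accession metadata + tree measurements,
#' replicate fruit bulks, per-fruit dimension subsamples) with the generating
#' latent values retained as ground truth, fully reproducible from the config
#' seed. Tree circumference is emitted as latent ground diameter x pi and the
#' two crown diameters average exactly to the latent crown value, so the
#' trait-derivation stage recovers the latents for tree traits.
#'
#' @param config a [germplasm_config()]
#' @return object of class `germplasm_collection`: list with data.frames
#'   `accessions`, `fruit_bulks`, `fruit_dimensions`, `truth` (per-accession
#'   latents), `truth_components` (per-trait generating variance components)
#'   and the `config`
#' @export
generate_collection <- function(config = germplasm_config()) {
  stopifnot(inherits(config, "germplasm_config"))
  comps <- .generating_components(config)
  sigma_among <- sqrt(stats::setNames(comps$sigma2_among, comps$trait))
  sigma_within <- sqrt(stats::setNames(comps$sigma2_within, comps$trait))

  means <- config$trait_means
  p0 <- means[["EdRt"]] / 100
  mu <- means
  mu[["EdRt"]] <- logit(p0)
  gaps <- config$region_gaps
  gaps[["EdRt"]] <- (gaps[["EdRt"]] / 100) / (p0 * (1 - p0))

  pops <- config$populations
  n_total <- sum(pops$n_accessions)
  w_ug <- sum(pops$n_accessions[pops$region == "UG"]) / n_total
  w_dg <- 1 - w_ug
  chol_C <- chol(config$trait_correlations)

  acc_list <- list(); bulk_list <- list(); dim_list <- list(); truth_list <- list()
  for (i in seq_len(nrow(pops))) {
    pop <- pops$name[i]; region <- pops$region[i]; n <- pops$n_accessions[i]
    set.seed(derive_seed(config$seed, pop))
    mu_pop <- if (region == "UG") mu + gaps * w_dg else mu - gaps * w_ug
    lat <- .draw_latents(n, mu_pop, sigma_among, chol_C)
    colnames(lat) <- .latent_traits
    ids <- sprintf("%s-%03d", pop, seq_len(n))

    habitat <- ifelse(stats::runif(n) < config$habitat_probs[[pop]],
                      "home_garden", "farm")
    age <- if (config$with_age) {
      round(pmin(pmax(stats::rlnorm(n, log(50), 0.5), 9), 150))
    } else rep(NA_real_, n)
    if (config$with_coordinates) {
      ctr <- .population_centers[match(pop, .population_centers$name), ]
      if (is.na(ctr$latitude)) ctr <- list(latitude = 6.5, longitude = 1.0)
      latd <- ctr$latitude + stats::rnorm(n, 0, 0.08)
      lond <- ctr$longitude + stats::rnorm(n, 0, 0.08)
    } else latd <- lond <- rep(NA_real_, n)

    half_sd <- pmin(0.3, lat[, "CrDiam"] / 4)
    crown_half <- stats::rnorm(n, 0, half_sd)
    for (iter in 1:1000) {
      bad <- abs(crown_half) >= lat[, "CrDiam"]
      if (!any(bad)) break
      crown_half[bad] <- stats::rnorm(sum(bad), 0, half_sd[bad])
    }
    acc_list[[pop]] <- data.frame(
      accession_id = ids, population = pop, region = region, habitat = habitat,
      age_years = age, latitude = latd, longitude = lond,
      circumference_ground_cm = lat[, "DiamGr"] * pi,
      height_m = lat[, "PlHgt"],
      crown_ns_m = lat[, "CrDiam"] + crown_half,
      crown_ew_m = lat[, "CrDiam"] - crown_half,
      stringsAsFactors = FALSE
    )

    nrep <- config$replicates_per_accession
    rep_fm <- .truncated_normal(n * nrep, rep(lat[, "AvFM"], each = nrep),
                                sigma_within[["AvFM"]])
    rep_logit <- stats::rnorm(n * nrep, rep(lat[, "EdRt"], each = nrep),
                              sigma_within[["EdRt"]])
    fm10 <- rep_fm * config$fruits_per_replicate
    sm10 <- fm10 * (1 - inv_logit(rep_logit))
    bulk_list[[pop]] <- data.frame(
      accession_id = rep(ids, each = nrep),
      replicate_id = rep(seq_len(nrep), times = n),
      n_fruits = config$fruits_per_replicate,
      fresh_mass_g = fm10, seed_mass_g = sm10,
      stringsAsFactors = FALSE
    )

    nd <- config$dimension_subsample
    len <- .truncated_normal(n * nd, rep(lat[, "AvFL"], each = nd),
                             sigma_within[["AvFL"]])
    wid <- .truncated_normal(n * nd, rep(lat[, "AvFW"], each = nd),
                             sigma_within[["AvFW"]])
    dim_list[[pop]] <- data.frame(
      accession_id = rep(ids, each = nd),
      fruit_id = rep(seq_len(nd), times = n),
      length_mm = len, width_mm = wid,
      stringsAsFactors = FALSE
    )

    truth_list[[pop]] <- data.frame(
      accession_id = ids, population = pop, region = region,
      DiamGr = lat[, "DiamGr"], PlHgt = lat[, "PlHgt"],
      CrDiam = lat[, "CrDiam"], AvFL = lat[, "AvFL"], AvFW = lat[, "AvFW"],
      AvFM = lat[, "AvFM"], EdRt_logit = lat[, "EdRt"],
      EdRt = 100 * inv_logit(lat[, "EdRt"]),
      stringsAsFactors = FALSE
    )
  }

  out <- list(
    accessions = do.call(rbind, c(acc_list, make.row.names = FALSE)),
    fruit_bulks = do.call(rbind, c(bulk_list, make.row.names = FALSE)),
    fruit_dimensions = do.call(rbind, c(dim_list, make.row.names = FALSE)),
    truth = do.call(rbind, c(truth_list, make.row.names = FALSE)),
    truth_components = comps,
    config = config
  )
  class(out) <- "germplasm_collection"
  out
}

#' @export
print.germplasm_collection <- function(x, ...) {
  cat("Synthetic germplasm collection\n")
  cat(sprintf("  accessions:       %d (%d populations, regions: %s)\n",
              nrow(x$accessions), length(unique(x$accessions$population)),
              paste(sort(unique(x$accessions$region)), collapse = "/")))
  cat(sprintf("  fruit bulks:      %d replicates of %d fruits\n",
              nrow(x$fruit_bulks), x$config$fruits_per_replicate))
  cat(sprintf("  fruit dimensions: %d measured fruits\n",
              nrow(x$fruit_dimensions)))
  invisible(x)
}

#' Simulate a single grouped trait with known repeatability
#'
#' Minimal replicate-structure generator for parameter-recovery and coverage
#' studies: accession latent values ~ N(group mean, sd_total * sqrt(R)),
#' observations = latent + N(0, sd_total * sqrt(1 - R)), optionally with fixed
#' group (population) mean shifts that an adjusted-repeatability fit must
#' remove.
#'
#' @param n_accessions,n_replicates design size
#' @param R generating repeatability in [0, 1]
#' @param mean,sd_total marginal observation mean and SD (within a group)
#' @param n_groups number of fixed-effect groups accessions are split across
#' @param group_effect_sd SD of the fixed group mean shifts
#' @param seed integer seed
#' @return data.frame with accession, group, replicate, latent, y
#' @export
simulate_trait_replicates <- function(n_accessions, n_replicates, R,
                                      mean = 0, sd_total = 1,
                                      n_groups = 1, group_effect_sd = 0,
                                      seed = 1L) {
  stopifnot(R >= 0, R <= 1, sd_total > 0)
  set.seed(as.integer(seed))
  group <- rep_len(seq_len(n_groups), n_accessions)
  geff <- stats::rnorm(n_groups, 0, group_effect_sd)
  latent <- stats::rnorm(n_accessions, mean + geff[group], sd_total * sqrt(R))
  y <- stats::rnorm(n_accessions * n_replicates,
                    rep(latent, each = n_replicates),
                    sd_total * sqrt(1 - R))
  data.frame(
    accession = rep(sprintf("A%04d", seq_len(n_accessions)), each = n_replicates),
    group = rep(sprintf("G%02d", group), each = n_replicates),
    replicate = rep(seq_len(n_replicates), times = n_accessions),
    latent = rep(latent, each = n_replicates),
    y = y,
    stringsAsFactors = FALSE
  )
}

#' Write a collection to a directory of CSV files
#'
#' Emits `accessions.csv`, `fruit_bulks.csv`, `fruit_dimensions.csv` with the
#' exact headers [read_collection()] expects, plus `truth.csv` (per-accession
#' latents) and `truth_components.csv` (generating variance components) when
#' ground truth is present.
#'
#' @param collection a `germplasm_collection` (truth optional)
#' @param directory output directory, created if needed
#' @return invisibly, the vector of files written
#' @export
write_collection <- function(collection, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory)) {
      stop("cannot create directory: ", directory)
    }
  }
  files <- c()
  emit <- function(df, name) {
    path <- file.path(directory, name)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    files <<- c(files, path)
  }
  emit(collection$accessions, "accessions.csv")
  emit(collection$fruit_bulks, "fruit_bulks.csv")
  emit(collection$fruit_dimensions, "fruit_dimensions.csv")
  if (!is.null(collection$truth)) emit(collection$truth, "truth.csv")
  if (!is.null(collection$truth_components)) {
    emit(collection$truth_components, "truth_components.csv")
  }
  invisible(files)
}
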