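# File contracts, configuration and the end-to-end pipeline runner. CSV
# throughout (RFC 4180 via read.csv/write.csv), empty string = missing, '.'
# decimal point; a JSON run manifest records config, per-stage outputs, file
# hashes, method choices and warnings so data-dependent decisions stay
# auditable.

.accessions_header <- c("accession_id", "population", "region", "habitat",
                        "age_years", "latitude", "longitude",
                        "circumference_ground_cm", "height_m",
                        "crown_ns_m", "crown_ew_m")
.bulks_header <- c("accession_id", "replicate_id", "n_fruits",
                   "fresh_mass_g", "seed_mass_g")
.dimensions_header <- c("accession_id", "fruit_id", "length_mm", "width_mm")

#' @keywords internal
.read_table <- function(path, required) {
  if (!file.exists(path)) stop("missing input file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(basename(path), " lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning(basename(path), ": ignoring unknown column(s): ",
            paste(extra, collapse = ", "))
    df <- df[required]
  }
  df
}

#' Read a collection from a directory of CSV files
#'
#' Expects `accessions.csv`, `fruit_bulks.csv` and `fruit_dimensions.csv`
#' with the documented headers. Unknown columns are ignored with a warning;
#' missing headers, dangling accession references and physically impossible
#' rows (non-positive masses or lengths, seed mass >= fruit mass) are
#' rejected with row numbers.
#'
#' @param directory path holding the three CSVs
#' @return list with accessions, fruit_bulks, fruit_dimensions (and truth if
#'   a truth.csv is present), of class `germplasm_collection`
#' @export
read_collection <- function(directory) {
  acc <- .read_table(file.path(directory, "accessions.csv"), .accessions_header)
  fb <- .read_table(file.path(directory, "fruit_bulks.csv"), .bulks_header)
  fd <- .read_table(file.path(directory, "fruit_dimensions.csv"),
                    .dimensions_header)

  if (anyDuplicated(acc$accession_id)) {
    stop("accessions.csv: duplicate accession_id values")
  }
  bad_region <- which(!acc$region %in% c("DG", "UG"))
  if (length(bad_region)) {
    stop("accessions.csv: unknown region at row(s) ",
         paste(utils::head(bad_region, 5), collapse = ", "))
  }
  check_pos <- function(df, col, file) {
    bad <- which(!is.na(df[[col]]) & df[[col]] <= 0)
    if (length(bad)) {
      stop(file, ": non-positive ", col, " at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  for (col in c("circumference_ground_cm", "height_m", "crown_ns_m",
                "crown_ew_m")) check_pos(acc, col, "accessions.csv")
  for (col in c("fresh_mass_g", "seed_mass_g")) {
    check_pos(fb, col, "fruit_bulks.csv")
  }
  for (col in c("length_mm", "width_mm")) {
    check_pos(fd, col, "fruit_dimensions.csv")
  }
  bad_mass <- which(fb$seed_mass_g >= fb$fresh_mass_g)
  if (length(bad_mass)) {
    stop("fruit_bulks.csv: seed mass >= fruit mass at row(s) ",
         paste(utils::head(bad_mass, 5), collapse = ", "))
  }
  check_refs <- function(df, file) {
    bad <- which(!df$accession_id %in% acc$accession_id)
    if (length(bad)) {
      stop(file, ": unknown accession_id at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  check_refs(fb, "fruit_bulks.csv")
  check_refs(fd, "fruit_dimensions.csv")

  out <- list(accessions = acc, fruit_bulks = fb, fruit_dimensions = fd)
  truth_path <- file.path(directory, "truth.csv")
  if (file.exists(truth_path)) {
    out$truth <- utils::read.csv(truth_path, stringsAsFactors = FALSE)
  }
  comp_path <- file.path(directory, "truth_components.csv")
  if (file.exists(comp_path)) {
    out$truth_components <- utils::read.csv(comp_path, stringsAsFactors = FALSE)
  }
  class(out) <- "germplasm_collection"
  out
}

#' Pipeline configuration
#'
#' Bundles every method policy and every seed the pipeline stages consume, so
#' a run is reproducible from config + inputs alone.
#'
#' @param seed master seed; stage seeds derive from it unless given explicitly
#' @param stages character vector of stages to run, a subset of
#'   derive, describe, group_tests, correlations, sma, hopkins, multivariate,
#'   repeatability, core, geo
#' @param method_policy "auto" (Shapiro-Wilk gate), "parametric" or
#'   "nonparametric" for group tests / correlations / whole-vs-core tests
#' @param normality_alpha gate level
#' @param retention_policy,retention_tau,retention_k PCA retention rule (see
#'   [retain_components()])
#' @param k_policy,k_fixed cluster-count rule (see [cluster_accessions()])
#' @param core_intensity sampling intensity in (0, 1)
#' @param core_restarts local-search restarts
#' @param n_boot bootstrap replicates for repeatability uncertainty
#' @param hopkins_m_fraction probe fraction for the Hopkins statistic
#' @param seeds optional named list overriding derived stage seeds (hopkins,
#'   cluster, core, bootstrap)
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c("derive", "describe", "group_tests",
                                       "correlations", "sma", "hopkins",
                                       "multivariate", "repeatability",
                                       "core", "geo"),
                            method_policy = "auto",
                            normality_alpha = 0.05,
                            retention_policy = "cumulative",
                            retention_tau = 0.80,
                            retention_k = 4L,
                            k_policy = "auto",
                            k_fixed = NULL,
                            core_intensity = 0.20,
                            core_restarts = 10L,
                            n_boot = 1000L,
                            hopkins_m_fraction = 0.1,
                            seeds = list()) {
  if (core_intensity <= 0 || core_intensity >= 1) {
    stop("core_intensity must lie in (0, 1)")
  }
  derived <- list(
    hopkins = derive_seed(seed, "hopkins"),
    cluster = derive_seed(seed, "cluster"),
    core = derive_seed(seed, "core"),
    bootstrap = derive_seed(seed, "bootstrap")
  )
  derived[names(seeds)] <- seeds
  structure(list(
    seed = as.integer(seed), stages = stages,
    method_policy = method_policy, normality_alpha = normality_alpha,
    retention_policy = retention_policy, retention_tau = retention_tau,
    retention_k = retention_k, k_policy = k_policy, k_fixed = k_fixed,
    core_intensity = core_intensity, core_restarts = as.integer(core_restarts),
    n_boot = as.integer(n_boot),
    hopkins_m_fraction = hopkins_m_fraction,
    seeds = derived
  ), class = "pipeline_config")
}

#' @keywords internal
.write_stage_csv <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- trait derivation, descriptive statistics,
#' group-effect tests with region contrasts, correlations, SMA allometry by
#' region, Hopkins clustering tendency, PCA + clustering + cluster profiles,
#' fruit-trait repeatability, core selection + quality evaluation, coordinate
#' export -- writing each stage's CSV outputs before the next begins and
#' recording a JSON manifest (config snapshot, package version, file hashes,
#' per-stage method choices and warnings). A failing stage is recorded in the
#' manifest and later stages that do not depend on it still run.
#'
#' @param input a `germplasm_collection` (from [generate_collection()] or
#'   [read_collection()]) or a directory path readable by [read_collection()]
#' @param out_dir output directory, created if needed
#' @param config a [pipeline_config()]
#' @return the manifest, invisibly (also written to manifest.json)
#' @export
run_pipeline <- function(input, out_dir, config = pipeline_config()) {
  if (is.character(input)) input <- read_collection(input)
  stopifnot(inherits(input, "germplasm_collection"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("corediv")),
    config = unclass(config),
    stages = list()
  )
  state <- new.env(parent = emptyenv())
  state$traits <- NULL; state$pca <- NULL; state$clusters <- NULL
  state$core <- NULL

  run_stage <- function(name, fn) {
    if (!name %in% config$stages) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(invisible())
    }
    warnings_seen <- character(0)
    res <- withCallingHandlers(
      tryCatch(fn(), error = function(e) e),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res),
                                       warnings = warnings_seen)
    } else {
      outputs <- res %||% character(0)
      hashes <- if (length(outputs)) {
        as.list(unname(tools::md5sum(outputs)))
      } else list()
      manifest$stages[[name]] <<- list(
        status = "ok", outputs = as.list(basename(outputs)),
        hashes = hashes, warnings = warnings_seen
      )
    }
    invisible()
  }

  run_stage("derive", function() {
    state$traits <- derive_traits(input$accessions, input$fruit_bulks,
                                  input$fruit_dimensions)
    .write_stage_csv(state$traits, out_dir, "traits.csv")
  })

  run_stage("describe", function() {
    if (is.null(state$traits)) stop("derive stage did not run")
    .write_stage_csv(describe_traits(state$traits), out_dir, "summary.csv")
  })

  run_stage("group_tests", function() {
    tm <- state$traits
    if (is.null(tm)) stop("derive stage did not run")
    rows <- list()
    for (t in trait_columns(tm)) {
      for (fac in c("habitat", "population")) {
        gt <- group_effect(tm, t, fac, method_policy = config$method_policy,
                           alpha = config$normality_alpha)
        rows[[paste(t, fac)]] <- data.frame(
          trait = t, factor = fac, method = gt$method,
          statistic = gt$statistic, p_value = gt$p_value,
          approximation = gt$approximation %||% "",
          stringsAsFactors = FALSE
        )
        # contrast DG vs UG only inside a significant population model
        if (fac == "population" && gt$p_value < 0.05) {
          rc <- region_contrast(tm, t)
          rows[[paste(t, "region")]] <- data.frame(
            trait = t, factor = "region_contrast", method = rc$method,
            statistic = rc$statistic, p_value = rc$p_value,
            approximation = "", stringsAsFactors = FALSE
          )
        }
      }
    }
    .write_stage_csv(do.call(rbind, rows), out_dir, "group_tests.csv")
  })

  run_stage("correlations", function() {
    tm <- state$traits
    if (is.null(tm)) stop("derive stage did not run")
    cm <- correlation_matrix(tm, method_policy = config$method_policy,
                             alpha = config$normality_alpha)
    traits <- rownames(cm$r)
    pairs <- which(upper.tri(cm$r), arr.ind = TRUE)
    df <- data.frame(
      trait_a = traits[pairs[, 1]], trait_b = traits[pairs[, 2]],
      r = cm$r[pairs], p_value = cm$p[pairs], n = cm$n[pairs],
      method = cm$method[pairs], stringsAsFactors = FALSE
    )
    .write_stage_csv(df, out_dir, "correlations.csv")
  })

  run_stage("sma", function() {
    tm <- state$traits
    if (is.null(tm)) stop("derive stage did not run")
    pairs <- list(c("AvFM", "AvSM"), c("AvFM", "AvFL"), c("AvFM", "AvFW"),
                  c("EdRt", "AvFM"), c("EdRt", "AvSM"), c("EdRt", "AvFL"),
                  c("EdRt", "AvFW"), c("AvSM", "AvFL"), c("AvSM", "AvFW"))
    rows <- lapply(pairs, function(pr) {
      cc <- stats::complete.cases(tm[[pr[1]]], tm[[pr[2]]])
      fit <- sma_fit(tm[[pr[2]]][cc], tm[[pr[1]]][cc], tm$region[cc])
      data.frame(
        y = pr[1], x = pr[2],
        slope_DG = fit$groups$slope[fit$groups$group == "DG"],
        slope_UG = fit$groups$slope[fit$groups$group == "UG"],
        common_slope = fit$common_slope$estimate,
        slope_p = fit$common_slope$p_value,
        elevation_p = fit$elevation_test$p_value,
        stringsAsFactors = FALSE
      )
    })
    .write_stage_csv(do.call(rbind, rows), out_dir, "sma.csv")
  })

  run_stage("hopkins", function() {
    tm <- state$traits
    if (is.null(tm)) stop("derive stage did not run")
    X <- as.data.frame(tm)[trait_columns(tm)]
    H <- hopkins_statistic(X, m_fraction = config$hopkins_m_fraction,
                           seed = config$seeds$hopkins)
    .write_stage_csv(
      data.frame(statistic = "hopkins_H", value = H,
                 note = "low values indicate clusterable data"),
      out_dir, "hopkins.csv")
  })

  run_stage("multivariate", function() {
    tm <- state$traits
    if (is.null(tm)) stop("derive stage did not run")
    pca <- trait_pca(tm)
    state$pca <- pca
    nc <- retain_components(pca, policy = config$retention_policy,
                            tau = config$retention_tau,
                            k = config$retention_k)
    cl <- cluster_accessions(pca, k_policy = config$k_policy,
                             k = config$k_fixed, seed = config$seeds$cluster,
                             n_components = nc)
    state$clusters <- cl
    profiles <- characterize_clusters(tm, cl)
    assoc <- cluster_factor_association(
      cl, tm$region[match(names(cl$assignment), tm$accession_id)])
    f1 <- .write_stage_csv(
      data.frame(trait = rownames(pca$loadings), round(pca$loadings, 6)),
      out_dir, "pca_loadings.csv")
    f2 <- .write_stage_csv(
      data.frame(accession_id = rownames(pca$scores),
                 pca$scores[, seq_len(nc), drop = FALSE],
                 explained_cum = cumsum(pca$explained)[nc]),
      out_dir, "pca_scores.csv")
    f3 <- .write_stage_csv(
      data.frame(accession_id = names(cl$assignment),
                 cluster = unname(cl$assignment)),
      out_dir, "clusters.csv")
    f4 <- .write_stage_csv(profiles, out_dir, "cluster_profiles.csv")
    f5 <- .write_stage_csv(
      data.frame(statistic = assoc$statistic, df = assoc$df,
                 p_value = assoc$p_value, factor = "region"),
      out_dir, "cluster_region_chisq.csv")
    c(f1, f2, f3, f4, f5)
  })

  run_stage("repeatability", function() {
    rows <- list()
    for (t in c("AvFL", "AvFW", "AvFM", "AvSM", "FrSh")) {
      long <- trait_replicates(input, t)
      est <- repeatability_estimate(long$y, long$accession_id, long$population,
                                    n_boot = config$n_boot,
                                    seed = config$seeds$bootstrap, trait = t)
      rows[[t]] <- est
    }
    long <- trait_replicates(input, "EdRt")
    rows[["EdRt"]] <- proportion_repeatability(
      long$y, long$accession_id, long$population,
      n_boot = config$n_boot, seed = config$seeds$bootstrap, trait = "EdRt")
    df <- do.call(rbind, lapply(rows, function(e) {
      data.frame(trait = e$trait, R_adj = e$R_adj, se = e$se,
                 ci_low = e$ci_low, ci_high = e$ci_high,
                 lrt_statistic = e$lrt_statistic, lrt_p = e$lrt_p,
                 sigma2_among = e$sigma2_among,
                 sigma2_within = e$sigma2_within,
                 n_accessions = e$n_accessions,
                 n_observations = e$n_observations,
                 approximation = e$approximation %||% "",
                 stringsAsFactors = FALSE)
    }))
    .write_stage_csv(df, out_dir, "repeatability.csv")
  })

  run_stage("core", function() {
    tm <- state$traits
    if (is.null(tm)) stop("derive stage did not run")
    gd <- gower_distances(tm)
    core <- select_core(gd, intensity = config$core_intensity,
                        seed = config$seeds$core,
                        restarts = config$core_restarts)
    state$core <- core
    idf <- file.path(out_dir, "core_ids.txt")
    writeLines(core$ids, idf)
    quality <- evaluate_core(tm, core$ids)
    tests <- compare_whole_core(tm, core$ids,
                                method_policy = config$method_policy)
    report <- merge(quality$per_trait, tests, by = "trait", sort = FALSE)
    f2 <- .write_stage_csv(report, out_dir, "core_report.csv")
    f3 <- .write_stage_csv(
      data.frame(statistic = names(quality$aggregates),
                 value = unname(quality$aggregates)),
      out_dir, "core_aggregates.csv")
    c(idf, f2, f3)
  })

  run_stage("geo", function() {
    core_ids <- if (!is.null(state$core)) state$core$ids else character(0)
    cl <- if (!is.null(state$clusters)) state$clusters$assignment else NULL
    geo <- export_geo(input$accessions, core_ids, cl)
    .write_stage_csv(geo, out_dir, "geo.csv")
  })

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Export accession coordinates for external mapping
#'
#' One row per accession with region, cluster membership and a core flag;
#' rows without coordinates are flagged, not dropped.
#'
#' @param accessions accession table with latitude/longitude columns
#' @param core_ids accession ids in the core (may be empty)
#' @param cluster_assignment optional named cluster vector
#' @return data.frame with accession_id, latitude, longitude, region,
#'   cluster, in_core, missing_coordinates
#' @export
export_geo <- function(accessions, core_ids = character(0),
                       cluster_assignment = NULL) {
  cl <- rep(NA_integer_, nrow(accessions))
  if (!is.null(cluster_assignment)) {
    cl <- unname(cluster_assignment[accessions$accession_id])
  }
  data.frame(
    accession_id = accessions$accession_id,
    latitude = accessions$latitude,
    longitude = accessions$longitude,
    region = accessions$region,
    cluster = cl,
    in_core = accessions$accession_id %in% core_ids,
    missing_coordinates = is.na(accessions$latitude) |
      is.na(accessions$longitude),
    stringsAsFactors = FALSE
  )
}
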