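# Published summary statistics for the West African Synsepalum dulcificum
# germplasm collection (203 accessions, 7 populations across the Dahomey Gap
# and Upper Guinea forest). These tables calibrate the synthetic generator and
# provide a worked reference for the core-quality statistics.

#' Reference trait summary for the S. dulcificum collection
#'
#' Descriptive statistics (n, min, max, mean, SD, CV\%) for the three
#' tree-traits and six fruit-traits of the published 203-accession
#' West African miracle berry collection. Tree-trait rows are at accession
#' level (n = 203); fruit-length/width/shape rows are at fruit level
#' (5 fruits x 203 accessions) and mass/edible-ratio rows at single-fruit
#' scale across all replicate bulks.
#'
#' @return data.frame with columns trait, n, min, max, mean, sd, cv
#' @examples
#' ref <- reference_trait_summary()
#' cv_from_moments(ref$mean, ref$sd) # reproduces ref$cv
#' @export
reference_trait_summary <- function() {
  data.frame(
    trait = c("DiamGr", "PlHgt", "CrDiam", "AvFL", "AvFW",
              "AvFM", "AvSM", "EdRt", "FrSh"),
    n    = c(203, 203, 203, 1015, 1015, 8875, 8875, 8875, 1015),
    min  = c(4.28, 0.86, 0.75, 13.04, 7.39, 0.43, 0.16, 45.25, 1.06),
    max  = c(68.78, 7.50, 8.80, 26.41, 18.30, 2.03, 0.60, 83.01, 2.39),
    mean = c(19.12, 3.47, 4.24, 18.86, 10.59, 1.09, 0.35, 66.99, 1.79),
    sd   = c(10.20, 1.27, 1.62, 1.82, 1.28, 0.28, 0.07, 7.17, 0.18),
    cv   = c(53.34, 36.59, 38.20, 9.65, 12.08, 25.68, 20.00, 10.70, 10.05),
    stringsAsFactors = FALSE
  )
}

#' Reference whole-vs-core summary for the S. dulcificum core collection
#'
#' Per-trait range, CV and mean of the published whole collection
#' (203 accessions) and of its 41-entry core collection, as reported for the
#' nine phenotypic traits. Feeding these to [core_quality_from_summary()]
#' reproduces the published core-quality statistics (aggregate CR 97.6\%,
#' MD 3.23\%). Variances are not included: the published variance cells are
#' internally inconsistent with the published CVs for two traits, so variances
#' are derived as (cv/100 x mean)^2 wherever needed.
#'
#' @return data.frame with columns trait, range_whole, range_core, cv_whole,
#'   cv_core, mean_whole, mean_core
#' @export
reference_core_summary <- function() {
  data.frame(
    trait = c("DiamGr", "PlHgt", "CrDiam", "AvFL", "AvFW",
              "AvFM", "AvSM", "EdRt", "FrSh"),
    range_whole = c(64.50, 6.64, 8.05, 13.37, 10.91, 1.60, 0.44, 37.76, 1.33),
    range_core  = c(62.68, 6.64, 7.05, 12.83, 10.91, 1.60, 0.43, 37.76, 1.33),
    cv_whole    = c(53.34, 36.59, 38.20, 9.65, 12.08, 25.68, 20.00, 10.70, 10.05),
    cv_core     = c(64.05, 45.88, 47.92, 14.06, 18.58, 32.06, 27.07, 13.53, 15.07),
    mean_whole  = c(19.12, 3.47, 4.23, 18.86, 10.59, 1.09, 0.35, 66.99, 1.79),
    mean_core   = c(22.33, 3.70, 4.23, 18.95, 10.82, 1.14, 0.35, 67.66, 1.78),
    stringsAsFactors = FALSE
  )
}

#' Default population layout of the reference collection
#'
#' Seven populations in two ecological regions: four in the Dahomey Gap (DG,
#' the savannah corridor) and three in the Upper Guinea forest block (UG),
#' with the published per-population accession counts (total 203).
#'
#' @return data.frame with columns name, region, n_accessions
#' @export
reference_populations <- function() {
  data.frame(
    name = c("Oueme", "Zou", "Mono", "Volta", "Eastern", "Central", "Western"),
    region = c("DG", "DG", "DG", "DG", "UG", "UG", "UG"),
    n_accessions = c(19L, 67L, 67L, 11L, 25L, 4L, 10L),
    stringsAsFactors = FALSE
  )
}

#' Reference fruit-trait repeatability estimates
#'
#' Published adjusted repeatability (intraclass correlation after removing
#' population fixed effects) for the six fruit traits. EdRt was estimated on
#' proportions and is carried here as a latent logit-scale target.
#'
#' @return named numeric vector of repeatabilities in (0,1)
#' @export
reference_repeatability <- function() {
  c(AvFL = 0.745, AvFW = 0.666, AvFM = 0.883,
    AvSM = 0.821, EdRt = 0.015, FrSh = 0.580)
}
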