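# Trait derivation: turn raw field measurements (tree metrics, replicate
# 10-fruit bulks, per-fruit dimensions) into the nine analysis traits, one row
# per accession, and summarize them.

.trait_codes <- c("DiamGr", "PlHgt", "CrDiam", "AvFL", "AvFW",
                  "AvFM", "AvSM", "EdRt", "FrSh")

#' Tree diameter at ground level from circumference
#'
#' DiamGr = C / pi, with C the circumference at ground level (cm).
#'
#' @param c_gr circumference at ground level in cm, strictly positive
#' @return diameter in cm
#' @examples
#' diameter_from_circumference(pi) # 1
#' @export
diameter_from_circumference <- function(c_gr) {
  if (any(!is.finite(c_gr)) || any(c_gr <= 0)) {
    stop("circumference must be strictly positive")
  }
  c_gr / pi
}

#' Edible ratio of a 10-fruit bulk
#'
#' EdRt = (FM10 - SM10) / FM10, the pulp share of fresh fruit mass, reported
#' on the percent scale.
#'
#' @param fm10 fresh mass of the 10-fruit bulk (g)
#' @param sm10 fresh seed mass of the same 10 fruits (g); 0 < sm10 < fm10
#' @return edible ratio in percent
#' @examples
#' edible_ratio(10, 5) # 50
#' @export
edible_ratio <- function(fm10, sm10) {
  if (any(!is.finite(fm10)) || any(!is.finite(sm10)) ||
      any(fm10 <= 0) || any(sm10 <= 0)) {
    stop("masses must be strictly positive")
  }
  if (any(sm10 >= fm10)) stop("seed mass must be smaller than fruit mass")
  (fm10 - sm10) / fm10 * 100
}

#' Fruit shape index
#'
#' FrSh = length / width; 1 is round, larger is more oblong.
#'
#' @param avfl average fruit length (mm)
#' @param avfw average fruit width (mm)
#' @return dimensionless shape index
#' @export
fruit_shape_index <- function(avfl, avfw) {
  if (any(!is.finite(avfl)) || any(!is.finite(avfw)) ||
      any(avfl <= 0) || any(avfw <= 0)) {
    stop("fruit dimensions must be strictly positive")
  }
  avfl / avfw
}

#' Derive the nine analysis traits per accession
#'
#' Replicate bulking follows the field protocol: AvFM and AvSM are the
#' replicate means of FM10 and SM10 divided by the bulk size (10); EdRt is the
#' mean of per-replicate edible ratios (not the ratio of summed masses);
#' AvFL/AvFW average all measured fruits of an accession and FrSh is their
#' ratio; CrDiam averages the two directional crown measures; DiamGr comes
#' from the circumference. Traits are derived independently, so an accession
#' can carry tree traits while fruit cells stay missing.
#'
#' @param accessions data.frame as in `accessions.csv` (see
#'   [read_collection()])
#' @param fruit_bulks data.frame of replicate bulks (fresh_mass_g,
#'   seed_mass_g, n_fruits)
#' @param fruit_dimensions data.frame of per-fruit length_mm / width_mm
#' @return a `trait_matrix`: data.frame with accession_id, population, region,
#'   habitat and the nine trait columns
#' @export
derive_traits <- function(accessions, fruit_bulks = NULL,
                          fruit_dimensions = NULL) {
  stopifnot(is.data.frame(accessions), nrow(accessions) >= 1)
  ids <- accessions$accession_id
  if (anyDuplicated(ids)) stop("duplicate accession ids")

  check_refs <- function(df, what) {
    if (is.null(df) || nrow(df) == 0) return(invisible())
    dangling <- setdiff(unique(df$accession_id), ids)
    if (length(dangling)) {
      stop(sprintf("%s references unknown accessions: %s", what,
                   paste(utils::head(dangling, 5), collapse = ", ")))
    }
  }
  check_refs(fruit_bulks, "fruit_bulks")
  check_refs(fruit_dimensions, "fruit_dimensions")

  out <- data.frame(
    accession_id = ids,
    population = accessions$population,
    region = accessions$region,
    habitat = accessions$habitat,
    stringsAsFactors = FALSE
  )
  out$DiamGr <- diameter_from_circumference(accessions$circumference_ground_cm)
  out$PlHgt <- accessions$height_m
  out$CrDiam <- (accessions$crown_ns_m + accessions$crown_ew_m) / 2

  for (t in c("AvFL", "AvFW", "AvFM", "AvSM", "EdRt", "FrSh")) out[[t]] <- NA_real_

  if (!is.null(fruit_bulks) && nrow(fruit_bulks) > 0) {
    fb <- fruit_bulks
    per_fruit <- fb$n_fruits
    avfm <- tapply(fb$fresh_mass_g / per_fruit, fb$accession_id, mean)
    avsm <- tapply(fb$seed_mass_g / per_fruit, fb$accession_id, mean)
    edrt <- tapply(edible_ratio(fb$fresh_mass_g, fb$seed_mass_g),
                   fb$accession_id, mean)
    out$AvFM[match(names(avfm), ids)] <- avfm
    out$AvSM[match(names(avsm), ids)] <- avsm
    out$EdRt[match(names(edrt), ids)] <- edrt
  }
  if (!is.null(fruit_dimensions) && nrow(fruit_dimensions) > 0) {
    fd <- fruit_dimensions
    avfl <- tapply(fd$length_mm, fd$accession_id, mean)
    avfw <- tapply(fd$width_mm, fd$accession_id, mean)
    out$AvFL[match(names(avfl), ids)] <- avfl
    out$AvFW[match(names(avfw), ids)] <- avfw
    out$FrSh <- fruit_shape_index_or_na(out$AvFL, out$AvFW)
  }

  missing_fruit <- is.na(out$AvFM) | is.na(out$AvFL)
  if (any(missing_fruit)) {
    warning(sprintf("%d accession(s) lack fruit replicates; fruit traits left missing",
                    sum(missing_fruit)))
  }
  class(out) <- c("trait_matrix", "data.frame")
  out
}

#' @keywords internal
fruit_shape_index_or_na <- function(l, w) {
  ok <- !is.na(l) & !is.na(w)
  res <- rep(NA_real_, length(l))
  if (any(ok)) res[ok] <- fruit_shape_index(l[ok], w[ok])
  res
}

#' @keywords internal
trait_columns <- function(matrix) {
  intersect(.trait_codes, names(matrix))
}

#' Descriptive statistics per trait
#'
#' n, min, max, mean, sample SD (n - 1) and CV\% = SD/mean x 100 per trait,
#' over non-missing accessions. All-missing traits are dropped with a warning.
#'
#' @param matrix a `trait_matrix` (or any data.frame holding trait columns)
#' @param traits trait columns to summarize (default: the nine standard codes
#'   present)
#' @return data.frame with one row per trait
#' @export
describe_traits <- function(matrix, traits = trait_columns(matrix)) {
  rows <- lapply(traits, function(t) {
    x <- matrix[[t]]
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      warning("trait ", t, " is entirely missing; omitted from summary")
      return(NULL)
    }
    data.frame(
      trait = t, n = length(x), min = min(x), max = max(x),
      mean = mean(x), sd = stats::sd(x),
      cv = if (mean(x) != 0) stats::sd(x) / mean(x) * 100 else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
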