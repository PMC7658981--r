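# Synthetic germplasm generator: reproducibility, structure, and convergence
# of the generated data to the configured moments.

test_that("default configuration reproduces the reference collection layout", {
  col <- generate_collection(germplasm_config(seed = 1))
  expect_equal(nrow(col$accessions), 203)
  expect_equal(sort(unique(col$accessions$population)),
               sort(reference_populations()$name))
  counts <- table(col$accessions$population)
  expect_equal(unname(counts[reference_populations()$name]),
               reference_populations()$n_accessions,
               ignore_attr = TRUE)
  expect_equal(nrow(col$fruit_bulks), 203 * 3)
  expect_equal(nrow(col$fruit_dimensions), 203 * 5)
  # referential integrity
  expect_true(all(col$fruit_bulks$accession_id %in% col$accessions$accession_id))
  expect_true(all(col$fruit_dimensions$accession_id %in% col$accessions$accession_id))
  # physically valid raw measurements
  expect_true(all(col$fruit_bulks$seed_mass_g > 0))
  expect_true(all(col$fruit_bulks$seed_mass_g < col$fruit_bulks$fresh_mass_g))
  expect_true(all(col$accessions$crown_ns_m > 0 & col$accessions$crown_ew_m > 0))
})

test_that("the same seed yields identical collections, different seeds differ", {
  a <- generate_collection(germplasm_config(seed = 42))
  b <- generate_collection(germplasm_config(seed = 42))
  c <- generate_collection(germplasm_config(seed = 43))
  expect_identical(a$accessions, b$accessions)
  expect_identical(a$fruit_bulks, b$fruit_bulks)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$fruit_bulks, c$fruit_bulks))
})

test_that("population streams are independent of the rest of the layout", {
  # region gaps zeroed so population means do not depend on the layout's
  # region weights; the per-population random streams must then be untouched
  # by adding a population
  gaps0 <- setNames(rep(0, 7), names(corediv:::.default_region_gaps))
  one <- generate_collection(small_config(seed = 5, region_gaps = gaps0))
  pops <- data.frame(name = c("Zou", "Eastern", "Extra"),
                     region = c("DG", "UG", "UG"),
                     n_accessions = c(12L, 8L, 6L))
  two <- generate_collection(small_config(seed = 5, populations = pops,
                                          region_gaps = gaps0))
  pick_zou <- function(col) {
    out <- col$fruit_bulks[grepl("^Zou", col$fruit_bulks$accession_id), ]
    rownames(out) <- NULL
    out
  }
  expect_identical(pick_zou(one), pick_zou(two))
})

test_that("zero within-accession variance makes replicates identical and R = 1", {
  col <- small_collection(seed = 2, repeatability_targets = c(
    AvFL = 1, AvFW = 1, AvFM = 1, EdRt = 1))
  per_acc <- tapply(col$fruit_bulks$fresh_mass_g,
                    col$fruit_bulks$accession_id, function(x) diff(range(x)))
  expect_true(all(per_acc < 1e-12))
  long <- trait_replicates(col, "AvFM")
  fit <- fit_variance_components(long$y, long$accession_id)
  expect_gt(adjusted_repeatability(fit), 1 - 1e-6)
})

test_that("generated replicate data recover the configured repeatability", {
  # large single-population design; ANOVA method-of-moments ICC as the
  # independent estimator
  cfg <- germplasm_config(
    seed = 9,
    populations = data.frame(name = "Zou", region = "DG", n_accessions = 500L),
    replicates_per_accession = 10L
  )
  col <- generate_collection(cfg)
  anova_icc <- function(y, g, k) {
    a <- stats::anova(stats::lm(y ~ g))
    msb <- a$`Mean Sq`[1]; msw <- a$`Mean Sq`[2]
    s_a <- (msb - msw) / k
    s_a / (s_a + msw)
  }
  long <- trait_replicates(col, "AvFM")
  expect_lt(abs(anova_icc(long$y, factor(long$accession_id), 10) - 0.883), 0.03)
  long <- trait_replicates(col, "EdRt")
  expect_lt(abs(anova_icc(log(long$y / (1 - long$y)),
                          factor(long$accession_id), 10) - 0.015), 0.03)
  long <- trait_replicates(col, "AvFL")
  expect_lt(abs(anova_icc(long$y, factor(long$accession_id), 5) - 0.745), 0.04)
})

test_that("latent accession correlations converge to the configured targets", {
  # Trait SDs kept well away from the positivity bound so the rejection
  # sampling leaves the MVN essentially untouched and convergence of the
  # correlation machinery itself is visible.
  cfg <- germplasm_config(
    seed = 21,
    populations = data.frame(name = "Zou", region = "DG", n_accessions = 2000L),
    trait_sds = c(DiamGr = 4, PlHgt = 0.7, CrDiam = 1.0)
  )
  col <- generate_collection(cfg)
  targets <- cfg$trait_correlations
  got <- cor(as.matrix(col$truth[, c("DiamGr", "PlHgt", "CrDiam", "AvFL",
                                     "AvFW", "AvFM", "EdRt_logit")]))
  dev <- abs(got - targets)
  key <- abs(targets) >= 0.3 & row(targets) != col(targets)
  expect_lt(max(dev[key]), 0.05)
  expect_lt(max(dev), 0.07)
})

test_that("default-config truncation attenuates correlations only mildly", {
  # Under the reference parameterization the tree traits sit 2-3 SDs from the
  # positivity bound; orthant conditioning then shrinks their correlations by
  # a few hundredths but must not reorganize the structure.
  cfg <- germplasm_config(
    seed = 22,
    populations = data.frame(name = "Zou", region = "DG", n_accessions = 1500L)
  )
  col <- generate_collection(cfg)
  got <- cor(as.matrix(col$truth[, c("DiamGr", "PlHgt", "CrDiam", "AvFL",
                                     "AvFW", "AvFM", "EdRt_logit")]))
  expect_lt(max(abs(got - cfg$trait_correlations)), 0.09)
})

test_that("region mean differences carry the configured signs", {
  col <- generate_collection(germplasm_config(seed = 4))
  tr <- col$truth
  gap <- function(t) mean(tr[[t]][tr$region == "UG"]) -
    mean(tr[[t]][tr$region == "DG"])
  expect_gt(gap("PlHgt"), 0)   # UG trees taller
  expect_gt(gap("AvFM"), 0)    # UG fruits heavier
  expect_gt(gap("AvFL"), 0)
  expect_gt(gap("AvFW"), 0)
  expect_gt(gap("EdRt"), 0)    # UG pulp share higher
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(germplasm_config(habitat_probs = 1.2), "habitat_probs")
  expect_error(germplasm_config(trait_sds = c(AvFM = -1)), "SD")
  expect_error(germplasm_config(repeatability_targets = c(AvFM = 0)),
               "repeatability")
  bad_C <- corediv:::.default_correlations
  bad_C["AvFM", "AvFW"] <- bad_C["AvFW", "AvFM"] <- -0.99
  bad_C["AvFM", "EdRt"] <- bad_C["EdRt", "AvFM"] <- 0.99
  bad_C["AvFW", "EdRt"] <- bad_C["EdRt", "AvFW"] <- 0.99
  expect_error(germplasm_config(trait_correlations = bad_C), "pair")
})

test_that("write/read round-trips a collection", {
  col <- small_collection(seed = 13)
  dir <- withr::local_tempdir()
  files <- write_collection(col, dir)
  expect_setequal(basename(files),
                  c("accessions.csv", "fruit_bulks.csv",
                    "fruit_dimensions.csv", "truth.csv",
                    "truth_components.csv"))
  back <- read_collection(dir)
  expect_equal(back$accessions, col$accessions, tolerance = 1e-10)
  expect_equal(back$fruit_bulks, col$fruit_bulks, tolerance = 1e-10)
  expect_equal(back$fruit_dimensions, col$fruit_dimensions, tolerance = 1e-10)
})

test_that("an empty collection writes headers only", {
  col <- small_collection(seed = 1)
  col$accessions <- col$accessions[0, ]
  col$fruit_bulks <- col$fruit_bulks[0, ]
  col$fruit_dimensions <- col$fruit_dimensions[0, ]
  col$truth <- NULL; col$truth_components <- NULL
  dir <- withr::local_tempdir()
  write_collection(col, dir)
  lines <- readLines(file.path(dir, "fruit_bulks.csv"))
  expect_length(lines, 1)
  expect_match(lines, "accession_id")
})
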