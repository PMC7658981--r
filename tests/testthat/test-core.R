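# Gower distances, E-NE core selection, and core-quality statistics.

test_that("Gower distance matches hand arithmetic and daisy", {
  tm <- data.frame(accession_id = c("a", "b", "c"),
                   AvFM = c(1, 2, 3), AvFL = c(10, 30, 20))
  gd <- gower_distances(tm, traits = c("AvFM", "AvFL"))
  # ranges: AvFM 2, AvFL 20
  expect_equal(gd$d["a", "b"], (1 / 2 + 20 / 20) / 2, tolerance = 1e-12)
  expect_equal(gd$d["a", "c"], (2 / 2 + 10 / 20) / 2, tolerance = 1e-12)
  expect_equal(gd$d["b", "c"], (1 / 2 + 10 / 20) / 2, tolerance = 1e-12)
  expect_equal(gd$d, t(gd$d))
  expect_equal(diag(gd$d), setNames(rep(0, 3), c("a", "b", "c")))

  skip_if_not_installed("cluster")
  set.seed(1)
  tm2 <- data.frame(accession_id = sprintf("x%02d", 1:15),
                    AvFM = runif(15), AvFL = runif(15, 10, 30),
                    PlHgt = runif(15, 1, 8))
  gd2 <- gower_distances(tm2, traits = c("AvFM", "AvFL", "PlHgt"))
  ref <- as.matrix(cluster::daisy(tm2[, -1], metric = "gower"))
  expect_equal(unname(gd2$d), unname(ref), tolerance = 1e-10)
})

test_that("Gower handles extremes, missing cells and degenerate traits", {
  tm <- data.frame(accession_id = c("lo", "hi"),
                   AvFM = c(0.4, 2.0), AvFL = c(13, 26), PlHgt = c(1, 7))
  gd <- gower_distances(tm, traits = c("AvFM", "AvFL", "PlHgt"))
  expect_equal(gd$d["lo", "hi"], 1) # opposite extremes on every trait
  tm2 <- data.frame(accession_id = c("a", "b", "c"),
                    AvFM = c(1, 2, 3), AvFL = c(10, NA, 20),
                    Const = c(5, 5, 5))
  expect_warning(gd2 <- gower_distances(tm2, traits = c("AvFM", "AvFL", "Const")),
                 "zero range")
  # a-b pair: only AvFM observed after dropping the constant trait
  expect_equal(gd2$d["a", "b"], (1 / 2) / 1)
  expect_equal(gd2$d["a", "c"], (2 / 2 + 10 / 10) / 2)
  tm3 <- data.frame(accession_id = c("a", "b", "c", "d"),
                    AvFM = c(1, 2, NA, NA), AvFL = c(NA, NA, 10, 20))
  expect_error(gower_distances(tm3, traits = c("AvFM", "AvFL")),
               "share no observed traits")
})

test_that("identical rows sit at distance zero; all-constant input errors", {
  tm <- data.frame(accession_id = c("a", "b", "c"),
                   AvFM = c(1, 1, 3), AvFL = c(2, 2, 8))
  gd <- gower_distances(tm, traits = c("AvFM", "AvFL"))
  expect_equal(gd$d["a", "b"], 0)
  tm2 <- data.frame(accession_id = c("a", "b"), AvFM = c(1, 1))
  expect_error(suppressWarnings(gower_distances(tm2, traits = "AvFM")),
               "no usable traits")
})

test_that("E-NE local search attains the exhaustive optimum on small problems", {
  hits <- 0
  for (i in 1:25) {
    D <- random_distance_matrix(10, seed = i)
    k <- 2 + (i %% 4)
    opt <- enumerate_core_optimum(D, k)
    res <- select_core(D, size = k, seed = i, restarts = 10)
    expect_lte(res$objective, opt$objective + 1e-12) # never exceeds
    if (abs(res$objective - opt$objective) < 1e-12) hits <- hits + 1
  }
  expect_gte(hits, 24)
})

test_that("core sizing, traces and edge cases behave as specified", {
  D <- random_distance_matrix(20, seed = 3)
  res <- select_core(D, size = 6, seed = 1, restarts = 3)
  expect_length(res$ids, 6)
  expect_false(anyDuplicated(res$ids) > 0)
  expect_true(all(diff(res$trace) > 0)) # monotone improvement
  # round-half-up sizing: 0.2 * 18 = 3.6 -> 4
  expect_length(select_core(D[1:18, 1:18], intensity = 0.2, seed = 1,
                            restarts = 2)$ids, 4)
  expect_error(select_core(D, size = 1), "at least 2")
  expect_warning(all_res <- select_core(D, size = 20), "whole set")
  expect_length(all_res$ids, 20)
  Ds <- D; diag(Ds) <- Inf
  expect_equal(all_res$objective, mean(apply(Ds, 1, min)), tolerance = 1e-12)
  # determinism
  r1 <- select_core(D, size = 5, seed = 7)
  r2 <- select_core(D, size = 5, seed = 7)
  expect_identical(r1$ids, r2$ids)
})

test_that("evaluate_core has the exact fixed point and subset-bounded CR", {
  tm <- small_traits(seed = 9)
  q <- evaluate_core(tm, tm$accession_id)
  expect_equal(unname(q$aggregates), c(100, 100, 0, 0), tolerance = 1e-10)
  set.seed(4)
  for (i in 1:5) {
    ids <- sample(tm$accession_id, 8)
    qi <- evaluate_core(tm, ids)
    expect_true(all(qi$per_trait$CR <= 100 + 1e-9))
  }
  # removing the accession defining a trait's range strictly lowers its CR
  hi <- tm$accession_id[which.max(tm$AvFM)]
  core_with <- c(hi, setdiff(tm$accession_id, hi)[1:7])
  core_without <- setdiff(tm$accession_id, hi)[1:8]
  cr_with <- evaluate_core(tm, core_with)$per_trait
  cr_without <- evaluate_core(tm, core_without)$per_trait
  expect_lt(cr_without$CR[cr_without$trait == "AvFM"],
            cr_with$CR[cr_with$trait == "AvFM"])
  expect_error(evaluate_core(tm, c("nope")), "subset")
})

test_that("summary-based quality agrees with raw-data quality", {
  tm <- small_traits(seed = 10)
  core_ids <- select_core(gower_distances(tm), size = 5, seed = 1,
                          restarts = 3)$ids
  q_raw <- evaluate_core(tm, core_ids)
  s <- q_raw$per_trait[, c("trait", "range_whole", "range_core", "cv_whole",
                           "cv_core", "mean_whole", "mean_core",
                           "var_whole", "var_core")]
  q_sum <- core_quality_from_summary(s)
  expect_equal(q_sum$aggregates, q_raw$aggregates, tolerance = 1e-10)
  expect_equal(q_sum$per_trait$VD, q_raw$per_trait$VD, tolerance = 1e-10)
})

test_that("whole-vs-core comparisons flag constructed bias and pass null cores", {
  tm <- small_traits(seed = 12, n_dg = 30, n_ug = 20)
  # deliberately biased core: the heaviest-fruit accessions
  top <- tm$accession_id[order(tm$AvFM, decreasing = TRUE)][1:10]
  res <- compare_whole_core(tm, top, traits = c("AvFM", "PlHgt"))
  expect_lt(res$p_value[res$trait == "AvFM"], 0.01)
  # core = whole: rank test cannot distinguish identical distributions
  res2 <- compare_whole_core(tm, tm$accession_id, traits = c("AvFM"),
                             method_policy = "nonparametric")
  expect_gt(res2$p_value, 0.99)
  # random cores from a homogeneous collection: mostly non-significant
  set.seed(5)
  ps <- replicate(10, {
    ids <- sample(tm$accession_id, 10)
    min(compare_whole_core(tm, ids, traits = c("AvFM", "AvFL", "PlHgt"))$p_value)
  })
  expect_gte(mean(ps > 0.05), 0.7)
})
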