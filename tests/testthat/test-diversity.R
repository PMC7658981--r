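# Group-effect tests, region contrast, correlations, SMA and Hopkins.

test_that("group_effect separates shifted groups and accepts identical ones", {
  set.seed(1)
  base <- rnorm(30)
  tm <- data.frame(accession_id = as.character(1:60),
                   habitat = rep(c("farm", "home_garden"), each = 30),
                   AvFM = c(base, base + 50))
  gt <- group_effect(tm, "AvFM", "habitat")
  expect_lt(gt$p_value, 0.001)
  expect_true(gt$method %in% c("welch_t", "mann_whitney_u"))

  tm$population <- rep(c("a", "b", "c"), 20)
  tm$AvFM <- rep(1:20, 3)
  gt2 <- group_effect(tm, "AvFM", "population",
                      method_policy = "nonparametric")
  expect_equal(gt2$method, "kruskal_wallis")
  expect_gt(gt2$p_value, 0.99)
})

test_that("Kruskal-Wallis agrees with the explicit rank-sum formula", {
  y <- c(2.1, 3.5, 1.2, 5.5, 4.4, 6.1, 0.3, 7.7, 2.9)
  g <- rep(c("a", "b", "c"), each = 3)
  tm <- data.frame(accession_id = as.character(1:9), AvFM = y, population = g)
  gt <- group_effect(tm, "AvFM", "population", method_policy = "nonparametric")
  # brute-force H from rank sums (no ties)
  r <- rank(y); n <- length(y)
  Rj <- tapply(r, g, sum); nj <- tapply(r, g, length)
  H <- 12 / (n * (n + 1)) * sum(Rj^2 / nj) - 3 * (n + 1)
  expect_equal(gt$statistic, unname(H), tolerance = 1e-12)
})

test_that("method policy can force the parametric branch", {
  tm <- small_traits(seed = 5)
  gt <- group_effect(tm, "AvFM", "population", method_policy = "parametric")
  expect_equal(gt$method, "welch_t") # two populations in the small fixture
  gt2 <- group_effect(tm, "EdRt", "habitat", method_policy = "parametric")
  expect_match(gt2$approximation, "logit")
})

test_that("region contrast matches the closed-form contrast t", {
  set.seed(2)
  tm <- data.frame(
    accession_id = as.character(1:18),
    population = rep(c("P1", "P2", "P3"), times = c(5, 6, 7)),
    region = rep(c("DG", "DG", "UG"), times = c(5, 6, 7)),
    AvFM = rnorm(18, mean = rep(c(1, 1.2, 1.8), times = c(5, 6, 7)), sd = 0.1)
  )
  rc <- region_contrast(tm, "AvFM")
  m <- tapply(tm$AvFM, tm$population, mean)
  nn <- tapply(tm$AvFM, tm$population, length)
  cc <- c(-0.5, -0.5, 1)
  s2 <- sum(unlist(lapply(split(tm$AvFM, tm$population),
                          function(v) (v - mean(v))^2))) / (18 - 3)
  t_hand <- sum(cc * m) / sqrt(s2 * sum(cc^2 / nn))
  expect_equal(rc$statistic, unname(t_hand), tolerance = 1e-12)
  expect_equal(rc$df, 15)

  # separated regions with tiny residual variance
  tm$AvFM <- rep(c(1, 1, 11), times = c(5, 6, 7)) + rnorm(18, 0, 1e-3)
  expect_lt(region_contrast(tm, "AvFM")$p_value, 0.001)
  # all population means equal: estimate ~ 0
  tm$AvFM <- rnorm(18, 5, 1e-8)
  expect_lt(abs(region_contrast(tm, "AvFM")$estimate), 1e-6)
  expect_error(region_contrast(within(tm, region <- "DG"), "AvFM"), "region")
})

test_that("correlation matrix is symmetric with sane p-values and methods", {
  set.seed(3)
  n <- 200
  x <- rnorm(n)
  tm <- data.frame(accession_id = as.character(1:n),
                   AvFM = x, AvFW = 2 * x, AvFL = rnorm(n),
                   FrSh = exp(x)) # monotone map of AvFM
  cm <- correlation_matrix(tm, traits = c("AvFM", "AvFW", "AvFL", "FrSh"))
  expect_equal(cm$r, t(cm$r))
  expect_true(all(cm$p >= 0 & cm$p <= 1, na.rm = TRUE))
  expect_equal(cm$r["AvFM", "AvFW"], 1, tolerance = 1e-12)
  expect_lt(abs(cm$r["AvFM", "AvFL"]), 0.2)
  sp <- correlation_matrix(tm, traits = c("AvFM", "FrSh"),
                           method_policy = "spearman")
  expect_equal(sp$r["AvFM", "FrSh"], 1)
  tm$AvFW <- 1
  expect_warning(correlation_matrix(tm, traits = c("AvFM", "AvFW")),
                 "constant")
})

test_that("SMA recovers exact lines and matches the moment formula", {
  x <- c(1, 2, 4, 7, 9)
  f <- sma_fit(x, 2 * x + 1)
  expect_equal(f$groups$slope, 2)
  expect_equal(f$groups$elevation, 1)

  set.seed(4)
  x <- rnorm(40); y <- -1.5 * x + rnorm(40, 0, 0.8)
  f2 <- sma_fit(x, y)
  r <- cor(x, y)
  expect_equal(f2$groups$slope, sign(r) * sd(y) / sd(x), tolerance = 1e-12)
  expect_equal(sign(f2$groups$slope), sign(r))

  # swap symmetry: b_yx * b_xy = 1
  f3 <- sma_fit(y, x)
  expect_equal(f2$groups$slope * f3$groups$slope, 1, tolerance = 1e-12)
})

test_that("duplicated groups give null slope and elevation tests", {
  set.seed(5)
  x <- rnorm(30); y <- 2 * x + 1 + rnorm(30, 0, 0.3)
  f <- sma_fit(c(x, x), c(y, y), rep(c("DG", "UG"), each = 30))
  expect_lt(f$common_slope$statistic, 1e-8)
  expect_lt(f$elevation_test$statistic, 1e-8)
  expect_equal(f$common_slope$df, 1)

  # a genuine elevation shift with a shared slope
  f2 <- sma_fit(c(x, x), c(y, y + 2), rep(c("DG", "UG"), each = 30))
  expect_gt(f2$common_slope$p_value, 0.05)
  expect_lt(f2$elevation_test$p_value, 0.001)

  # grossly different slopes are detected and block the elevation test
  f3 <- sma_fit(c(x, x), c(y, 5 * x + rnorm(30, 0, 0.3)),
                rep(c("DG", "UG"), each = 30))
  expect_lt(f3$common_slope$p_value, 0.01)
  expect_true(is.na(f3$elevation_test$statistic))
})

test_that("Hopkins statistic is ~0.5 under uniformity and low for clusters", {
  set.seed(6)
  hs <- vapply(1:10, function(s) {
    hopkins_statistic(matrix(runif(600), 300, 2), seed = s)
  }, 0)
  expect_lt(abs(mean(hs) - 0.5), 0.06)
  clustered <- rbind(matrix(rnorm(200, 0, 0.05), 100, 2),
                     matrix(rnorm(200, 5, 0.05), 100, 2))
  h_cl <- hopkins_statistic(clustered, seed = 1)
  expect_lt(h_cl, 0.25)
  expect_lt(h_cl, min(hs)) # clustered below every uniform draw
  expect_error(hopkins_statistic(matrix(1, 20, 2)), "identical")
  expect_error(hopkins_statistic(matrix(runif(10), 5, 2)), "at least 10")
  # determinism
  X <- matrix(runif(100), 50, 2)
  expect_identical(hopkins_statistic(X, seed = 3), hopkins_statistic(X, seed = 3))
})
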