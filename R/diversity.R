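# Group-effect tests, region contrast, correlation structure and clustering
# tendency. The parametric-vs-rank choice ("where relevant") is automated by a
# per-group Shapiro-Wilk gate at a configurable alpha, overridable by policy.

#' @keywords internal
.normality_ok <- function(values, by = NULL, alpha = 0.05) {
  groups <- if (is.null(by)) list(values) else split(values, by)
  for (g in groups) {
    g <- g[!is.na(g)]
    if (length(g) < 3 || length(unique(g)) < 3) next
    if (length(g) > 4999) g <- g[seq(1, length(g), length.out = 4999)]
    if (stats::shapiro.test(g)$p.value < alpha) return(FALSE)
  }
  TRUE
}

#' Test a grouping factor's effect on one trait
#'
#' Two-level factors get a Welch t-test or a Mann-Whitney U; multi-level
#' factors a one-way ANOVA F or a Kruskal-Wallis H. With
#' `method_policy = "auto"` the parametric branch is used only when every
#' group passes a Shapiro-Wilk normality check at `alpha`. The edible ratio,
#' being a proportion, is analysed on the logit scale when
#' `logit_proportion = TRUE` (percent values are rescaled to (0,1) first);
#' the output records this as an approximation to a quasi-binomial model.
#'
#' @param matrix a `trait_matrix`
#' @param trait trait column name
#' @param factor grouping column name (e.g. "habitat", "population")
#' @param method_policy "auto", "parametric" or "nonparametric"
#' @param alpha Shapiro-Wilk gate level for "auto"
#' @param logit_proportion analyse EdRt-style percent traits on the logit scale
#' @return object of class `group_test`: trait, factor, method, statistic,
#'   p_value, group means, n per group
#' @export
group_effect <- function(matrix, trait, factor,
                         method_policy = c("auto", "parametric", "nonparametric"),
                         alpha = 0.05,
                         logit_proportion = identical(trait, "EdRt")) {
  method_policy <- match.arg(method_policy)
  y <- matrix[[trait]]
  g <- as.factor(matrix[[factor]])
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(g[keep])
  approximation <- NULL
  if (logit_proportion) {
    y <- logit(pmin(pmax(y / 100, 1e-6), 1 - 1e-6))
    approximation <- "logit-scale analysis standing in for a quasi-binomial GLM"
  }
  sizes <- table(g)
  if (length(sizes) < 2) stop("need at least two groups for trait ", trait)
  if (any(sizes < 2)) {
    stop("degenerate group(s) with < 2 observations: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  parametric <- switch(method_policy,
    parametric = TRUE, nonparametric = FALSE,
    auto = .normality_ok(y, g, alpha)
  )
  if (length(sizes) == 2) {
    if (parametric) {
      ht <- stats::t.test(y ~ g)
      method <- "welch_t"
    } else {
      ht <- suppressWarnings(stats::wilcox.test(y ~ g))
      method <- "mann_whitney_u"
    }
  } else {
    if (parametric) {
      ht <- summary(stats::aov(y ~ g))[[1]]
      ht <- list(statistic = ht[1, "F value"], p.value = ht[1, "Pr(>F)"])
      method <- "anova_f"
    } else {
      ht <- stats::kruskal.test(y, g)
      method <- "kruskal_wallis"
    }
  }
  structure(list(
    trait = trait, factor = factor, method = method,
    statistic = unname(ht$statistic), p_value = unname(ht$p.value),
    group_means = tapply(y, g, mean), group_n = as.vector(sizes),
    approximation = approximation
  ), class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("Group effect of %s on %s: %s statistic = %.4g, p = %.4g\n",
              x$factor, x$trait, x$method, x$statistic, x$p_value))
  invisible(x)
}

#' Ecological-region contrast within the population model
#'
#' Linear contrast of the mean of UG population means against the mean of DG
#' population means, inside the one-way population ANOVA: estimate
#' L = mean(mu_UG) - mean(mu_DG), t = L / sqrt(s2 * sum(c_i^2 / n_i)) with
#' N - g residual degrees of freedom.
#'
#' @param matrix a `trait_matrix` with population and region columns
#' @param trait trait column name
#' @return object of class `group_test` with the contrast estimate attached
#' @export
region_contrast <- function(matrix, trait) {
  y <- matrix[[trait]]
  pop <- as.factor(matrix$population)
  keep <- !is.na(y)
  y <- y[keep]; pop <- droplevels(pop[keep])
  region_of <- tapply(as.character(matrix$region[keep]), pop,
                      function(r) r[1])
  pops <- levels(pop)
  is_ug <- region_of[pops] == "UG"
  if (!any(is_ug) || all(is_ug)) stop("both regions must contribute populations")
  ni <- as.vector(table(pop))
  mi <- as.vector(tapply(y, pop, mean))
  cc <- ifelse(is_ug, 1 / sum(is_ug), -1 / sum(!is_ug))
  N <- length(y); g <- length(pops)
  s2 <- sum((y - mi[as.integer(pop)])^2) / (N - g)
  estimate <- sum(cc * mi)
  se <- sqrt(s2 * sum(cc^2 / ni))
  tval <- estimate / se
  p <- 2 * stats::pt(abs(tval), df = N - g, lower.tail = FALSE)
  structure(list(
    trait = trait, factor = "region_contrast", method = "linear_contrast_t",
    statistic = tval, p_value = p, estimate = estimate, se = se,
    df = N - g, group_means = stats::setNames(mi, pops),
    group_n = ni, approximation = NULL
  ), class = "group_test")
}

#' Pairwise trait correlation matrix
#'
#' Pearson's r for pairs where both traits pass a Shapiro-Wilk normality check
#' (policy "auto"), Spearman's rho otherwise; two-sided p-values from
#' [stats::cor.test()]; pairwise-complete observations. Constant traits give
#' NA with a warning.
#'
#' @param matrix a `trait_matrix`
#' @param traits trait columns to correlate
#' @param method_policy "auto", "pearson" or "spearman"
#' @param alpha normality gate level for "auto"
#' @return object of class `trait_correlations` with matrices r, p, n and the
#'   method used per pair
#' @export
correlation_matrix <- function(matrix, traits = trait_columns(matrix),
                               method_policy = c("auto", "pearson", "spearman"),
                               alpha = 0.05) {
  method_policy <- match.arg(method_policy)
  k <- length(traits)
  normal <- vapply(traits, function(t) {
    .normality_ok(matrix[[t]][!is.na(matrix[[t]])], alpha = alpha)
  }, logical(1))
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  meth <- matrix(NA_character_, k, k, dimnames = list(traits, traits))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    x <- matrix[[traits[i]]]; y <- matrix[[traits[j]]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) stop("need >= 3 complete pairs for ",
                          traits[i], " vs ", traits[j])
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warning("constant trait in pair ", traits[i], "/", traits[j],
              "; correlation undefined")
      next
    }
    m <- switch(method_policy,
      pearson = "pearson", spearman = "spearman",
      auto = if (normal[i] && normal[j]) "pearson" else "spearman"
    )
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = m))
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
    n[i, j] <- n[j, i] <- sum(ok)
    meth[i, j] <- meth[j, i] <- m
  }
  structure(list(r = r, p = p, n = n, method = meth),
            class = "trait_correlations")
}

#' @export
print.trait_correlations <- function(x, digits = 2, ...) {
  cat("Trait correlation matrix (r):\n")
  print(round(x$r, digits))
  invisible(x)
}

#' Hopkins clustering-tendency statistic
#'
#' Compares nearest-neighbour distances of m sampled real points (w) against
#' m uniform points over the data bounding box (u), on internally
#' standardized coordinates: H = sum(w) / (sum(u) + sum(w)). Orientation:
#' H near 0.5 means spatially unstructured data, H near 0 means clusterable
#' data (the convention of the source analyses; part of the literature uses
#' the reciprocal orientation).
#'
#' @param matrix numeric matrix or data.frame of accession coordinates
#'   (e.g. trait columns); standardized internally
#' @param m_fraction fraction of rows sampled as probes; m = max(10,
#'   ceiling(m_fraction * n))
#' @param seed integer seed for probe and uniform sampling
#' @return H in [0, 1]
#' @export
hopkins_statistic <- function(matrix, m_fraction = 0.1, seed = 1L) {
  X <- as.matrix(matrix)
  storage.mode(X) <- "double"
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  if (n < 10) stop("need at least 10 complete rows")
  rng <- apply(X, 2, function(c) diff(range(c)))
  if (all(rng == 0)) stop("degenerate data: all points identical")
  keep <- rng > 0
  X <- X[, keep, drop = FALSE]
  X <- scale(X)
  set.seed(as.integer(seed))
  m <- max(10L, ceiling(m_fraction * n))
  m <- min(m, n - 1L)
  probes <- sample.int(n, m)
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  U <- sapply(seq_along(lo), function(j) stats::runif(m, lo[j], hi[j]))
  U <- matrix(U, nrow = m)

  nn_dist <- function(P, Q, exclude_self = FALSE) {
    # smallest Euclidean distance from each row of P to rows of Q
    d2 <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * P %*% t(Q)
    d2[d2 < 0] <- 0
    if (exclude_self) d2[cbind(seq_len(nrow(P)), probes)] <- Inf
    sqrt(apply(d2, 1, min))
  }
  w <- nn_dist(X[probes, , drop = FALSE], X, exclude_self = TRUE)
  u <- nn_dist(U, X)
  denom <- sum(u) + sum(w)
  if (denom == 0) stop("degenerate data: zero nearest-neighbour distances")
  sum(w) / denom
}
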