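# Adjusted repeatability (broad-sense heritability proxy) of replicate-
# measured traits: random-intercept linear mixed model y = X beta + u_acc + e
# fitted by REML, with the variance ratio lambda = s2_among / s2_within
# profiled out by one-dimensional bounded optimization. Uncertainty by
# parametric bootstrap; significance by a boundary-corrected likelihood
# ratio test.

# REML profile pieces for a given log-lambda. All group algebra is closed
# form because (I + lambda J_k)^-1 = I - lambda/(1 + k lambda) J_k.
#' @keywords internal
.reml_profile <- function(loglambda, y, gidx, X, ksizes) {
  lambda <- exp(loglambda)
  a <- lambda / (1 + ksizes * lambda)         # per-group shrinkage
  gs_y <- rowsum(y, gidx)                     # group sums
  gs_X <- rowsum(X, gidx)
  XtViX <- crossprod(X) - crossprod(gs_X * a, gs_X)
  XtViy <- crossprod(X, y) - crossprod(gs_X * a, gs_y)
  ytViy <- sum(y^2) - sum(a * gs_y^2)
  ch <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(ch)) return(list(crit = Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), XtViy))
  rss <- max(ytViy - sum(beta * XtViy), 1e-300)
  n <- length(y); p <- ncol(X)
  s2w <- rss / (n - p)
  crit <- (n - p) * log(s2w) + sum(log1p(ksizes * lambda)) +
    2 * sum(log(diag(ch)))
  list(crit = crit, beta = drop(beta), s2w = s2w, lambda = lambda,
       gs_y = gs_y, a = a)
}

#' Fit a single-random-effect variance-components model by REML
#'
#' Random accession intercept, optional fixed factor (the "adjusted"
#' convention removes e.g. population means before partitioning variance).
#' The REML criterion is profiled over log(lambda), lambda the among/within
#' variance ratio, and minimized by bounded scalar search; a negative
#' among-component solution collapses to the boundary lambda = 0.
#'
#' @param y numeric response (one row per replicate observation)
#' @param accession_ids replicate-to-accession mapping
#' @param fixed_factor optional fixed-effect factor (same length as y),
#'   e.g. provenance population; accessions must be nested within its levels
#' @return object of class `vc_fit` with sigma2_among, sigma2_within, beta,
#'   REML log-likelihood, and the design bookkeeping needed for simulation
#' @export
fit_variance_components <- function(y, accession_ids, fixed_factor = NULL) {
  keep <- !is.na(y) & !is.na(accession_ids)
  if (!is.null(fixed_factor)) keep <- keep & !is.na(fixed_factor)
  y <- as.numeric(y[keep])
  acc <- droplevels(as.factor(accession_ids[keep]))
  ksizes_all <- table(acc)
  if (nlevels(acc) < 2) stop("need at least two accessions")
  if (sum(ksizes_all >= 2) < 2) {
    stop("need at least two accessions with two or more replicates")
  }
  if (!is.null(fixed_factor)) {
    ff <- droplevels(as.factor(fixed_factor[keep]))
    nest <- tapply(as.integer(ff), acc, function(v) length(unique(v)))
    if (any(nest > 1)) {
      stop("accessions must be nested within the fixed factor; violated by: ",
           paste(utils::head(names(nest)[nest > 1], 5), collapse = ", "))
    }
    X <- stats::model.matrix(~ff)
  } else {
    ff <- NULL
    X <- matrix(1, length(y), 1)
  }
  gidx <- as.integer(acc)
  ksizes <- as.vector(ksizes_all)

  obj <- function(ll) .reml_profile(ll, y, gidx, X, ksizes)$crit
  opt <- stats::optimize(obj, lower = -30, upper = 30, tol = 1e-10)
  at_zero <- .reml_profile(-Inf, y, gidx, X, ksizes)
  at_opt <- .reml_profile(opt$minimum, y, gidx, X, ksizes)
  use_zero <- at_zero$crit <= at_opt$crit + 1e-10
  fit <- if (use_zero) at_zero else at_opt
  lambda <- if (use_zero) 0 else fit$lambda
  n <- length(y); p <- ncol(X)
  loglik <- -0.5 * (fit$crit + (n - p) * (1 + log(2 * pi)))

  structure(list(
    sigma2_among = lambda * fit$s2w,
    sigma2_within = fit$s2w,
    lambda = lambda,
    beta = fit$beta,
    logLik_reml = loglik,
    crit = fit$crit,
    y = y, accession = acc, fixed = ff, X = X,
    n_accessions = nlevels(acc), n_observations = n
  ), class = "vc_fit")
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf(
    "Variance components (REML): among = %.5g, within = %.5g (R = %.3f)\n",
    x$sigma2_among, x$sigma2_within, adjusted_repeatability(x)))
  invisible(x)
}

#' Adjusted repeatability from a variance-components fit
#'
#' R = sigma2_among / (sigma2_among + sigma2_within). Fixed-effect variance
#' (e.g. among populations) is excluded from the denominator -- the
#' "adjusted" convention.
#'
#' @param fit a `vc_fit`
#' @return repeatability in [0, 1]
#' @export
adjusted_repeatability <- function(fit) {
  tot <- fit$sigma2_among + fit$sigma2_within
  if (tot <= 0) {
    warning("both variance components are zero; repeatability undefined")
    return(NA_real_)
  }
  fit$sigma2_among / tot
}

#' @keywords internal
.simulate_from_fit <- function(fit) {
  mu <- drop(fit$X %*% fit$beta)
  u <- stats::rnorm(fit$n_accessions, 0, sqrt(fit$sigma2_among))
  mu + u[as.integer(fit$accession)] +
    stats::rnorm(fit$n_observations, 0, sqrt(fit$sigma2_within))
}

#' Parametric-bootstrap uncertainty for repeatability
#'
#' Simulates `n_boot` datasets from the fitted model on the same design,
#' refits each, and returns the SD of the bootstrap repeatability estimates
#' and the 2.5/97.5 percentile interval.
#'
#' @param fit a `vc_fit`
#' @param n_boot number of bootstrap datasets (the reference analyses used
#'   1000)
#' @param seed integer seed
#' @return list with se, ci (length 2), estimates, n_failed
#' @export
bootstrap_uncertainty <- function(fit, n_boot = 1000, seed = 1L) {
  set.seed(as.integer(seed))
  est <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    yb <- .simulate_from_fit(fit)
    fb <- tryCatch(
      fit_variance_components(yb, fit$accession, fit$fixed),
      error = function(e) NULL
    )
    if (!is.null(fb)) est[b] <- adjusted_repeatability(fb)
  }
  n_failed <- sum(is.na(est))
  if (n_failed > 0.05 * n_boot) {
    warning(sprintf("%d of %d bootstrap refits failed", n_failed, n_boot))
  }
  ok <- est[!is.na(est)]
  list(se = stats::sd(ok),
       ci = unname(stats::quantile(ok, c(0.025, 0.975), type = 7)),
       estimates = est, n_failed = n_failed)
}

#' Likelihood-ratio significance of the accession variance component
#'
#' 2 x (REML log-likelihood of the full model minus that of the model without
#' the accession random effect), both with identical fixed effects. The null
#' sits on the boundary of the parameter space, so p comes from the
#' half-and-half chi-square mixture 0.5 chi2_0 + 0.5 chi2_1.
#'
#' @param fit a `vc_fit`
#' @return list with statistic and p_value
#' @export
lrt_significance <- function(fit) {
  gidx <- as.integer(fit$accession)
  ksizes <- as.vector(table(fit$accession))
  reduced <- .reml_profile(-Inf, fit$y, gidx, fit$X, ksizes)
  stat <- reduced$crit - fit$crit
  if (stat < -1e-6) stop("reduced model out-likelihooded the full model; ",
                         "numerical failure")
  stat <- max(stat, 0)
  p <- if (stat == 0) 1 else 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE)
  list(statistic = stat, p_value = p)
}

#' One-call adjusted repeatability estimate for a replicate-measured trait
#'
#' Convenience wrapper: REML fit, point estimate, parametric-bootstrap SE/CI
#' and boundary-corrected LRT, mirroring the usual repeatability report
#' (R, S.E., 95\% CI, LRT p).
#'
#' @inheritParams fit_variance_components
#' @param n_boot bootstrap replicates (0 skips the bootstrap)
#' @param seed bootstrap seed
#' @param trait optional trait label carried into the result
#' @return object of class `repeatability_estimate`
#' @export
repeatability_estimate <- function(y, accession_ids, fixed_factor = NULL,
                                   n_boot = 1000, seed = 1L, trait = NA_character_) {
  fit <- fit_variance_components(y, accession_ids, fixed_factor)
  R <- adjusted_repeatability(fit)
  lrt <- lrt_significance(fit)
  boot <- if (n_boot > 0) bootstrap_uncertainty(fit, n_boot, seed) else NULL
  structure(list(
    trait = trait, R_adj = R,
    se = if (is.null(boot)) NA_real_ else boot$se,
    ci_low = if (is.null(boot)) NA_real_ else boot$ci[1],
    ci_high = if (is.null(boot)) NA_real_ else boot$ci[2],
    lrt_statistic = lrt$statistic, lrt_p = lrt$p_value,
    sigma2_among = fit$sigma2_among, sigma2_within = fit$sigma2_within,
    n_accessions = fit$n_accessions, n_observations = fit$n_observations,
    approximation = NULL, fit = fit
  ), class = "repeatability_estimate")
}

#' @export
print.repeatability_estimate <- function(x, ...) {
  cat(sprintf("Repeatability%s: R_adj = %.3f (SE %.3f, 95%% CI [%.3f, %.3f]), LRT p = %.3g\n",
              if (is.na(x$trait)) "" else paste0(" of ", x$trait),
              x$R_adj, x$se, x$ci_low, x$ci_high, x$lrt_p))
  if (!is.null(x$approximation)) cat("  note:", x$approximation, "\n")
  invisible(x)
}

#' Repeatability of a proportion trait on the logit scale
#'
#' Proportion traits (the edible ratio) are mapped to the logit scale and
#' analysed with the Gaussian REML machinery; the estimate is a latent-scale
#' repeatability and the output flags the approximation (a binomial GLMM is
#' not identifiable here because a mass ratio has no binomial denominator).
#' Values at exactly 0 or 1 are clamped to (eps, 1 - eps) with a warning.
#'
#' @param proportion trait values in (0, 1) (rescale percents first)
#' @inheritParams repeatability_estimate
#' @param eps clamping margin
#' @return object of class `repeatability_estimate` with the approximation
#'   note set
#' @export
proportion_repeatability <- function(proportion, accession_ids,
                                     fixed_factor = NULL, n_boot = 1000,
                                     seed = 1L, trait = NA_character_,
                                     eps = 1e-6) {
  if (any(proportion < 0 | proportion > 1, na.rm = TRUE)) {
    stop("proportions must lie in [0, 1]; rescale percent values first")
  }
  clamped <- proportion <= 0 | proportion >= 1
  if (any(clamped, na.rm = TRUE)) {
    warning(sum(clamped, na.rm = TRUE), " value(s) at 0 or 1 clamped")
    proportion <- pmin(pmax(proportion, eps), 1 - eps)
  }
  res <- repeatability_estimate(logit(proportion), accession_ids, fixed_factor,
                                n_boot = n_boot, seed = seed, trait = trait)
  res$approximation <-
    "Gaussian REML on logit-transformed proportions; R is on the latent (logit) scale"
  res
}

#' Replicate-level observations of one fruit trait
#'
#' Builds the long table (y, accession, population) the repeatability fits
#' consume. Mass traits come from the replicate bulks (per-fruit averages,
#' proportion for EdRt), dimension traits from the per-fruit subsample
#' (FrSh as the per-fruit length/width ratio).
#'
#' @param collection a `germplasm_collection` or a list with accessions,
#'   fruit_bulks, fruit_dimensions
#' @param trait one of AvFL, AvFW, AvFM, AvSM, EdRt, FrSh
#' @return data.frame with accession_id, population, y (EdRt as a proportion)
#' @export
trait_replicates <- function(collection, trait) {
  acc <- collection$accessions
  pop_of <- stats::setNames(acc$population, acc$accession_id)
  if (trait %in% c("AvFM", "AvSM", "EdRt")) {
    fb <- collection$fruit_bulks
    y <- switch(trait,
      AvFM = fb$fresh_mass_g / fb$n_fruits,
      AvSM = fb$seed_mass_g / fb$n_fruits,
      EdRt = (fb$fresh_mass_g - fb$seed_mass_g) / fb$fresh_mass_g
    )
    ids <- fb$accession_id
  } else if (trait %in% c("AvFL", "AvFW", "FrSh")) {
    fd <- collection$fruit_dimensions
    y <- switch(trait,
      AvFL = fd$length_mm,
      AvFW = fd$width_mm,
      FrSh = fd$length_mm / fd$width_mm
    )
    ids <- fd$accession_id
  } else {
    stop("no replicate structure for trait ", trait)
  }
  data.frame(accession_id = ids, population = unname(pop_of[ids]), y = y,
             stringsAsFactors = FALSE)
}
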