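#' @keywords internal
logit <- function(p) log(p / (1 - p))

#' @keywords internal
inv_logit <- function(x) 1 / (1 + exp(-x))

# Deterministic 31-bit stream seed derived from a master seed and a label, so
# per-population (or per-restart) streams are independent of list order.
#' @keywords internal
derive_seed <- function(master_seed, label) {
  codes <- utf8ToInt(as.character(label))
  h <- as.double(master_seed %% 2147483647L)
  for (c in codes) {
    h <- (h * 131 + c) %% 2147483647
  }
  as.integer(h)
}

# Sample-variance helpers used consistently across the package (n - 1).
#' @keywords internal
cv_percent <- function(x) stats::sd(x) / mean(x) * 100

#' Coefficient of variation from first two moments
#'
#' CV(%) = sd / mean x 100, the convention used throughout trait summaries and
#' the core-quality variable rate. Exposed so published mean/SD pairs can be
#' turned into CVs without raw data.
#'
#' @param mean trait mean (must be non-zero)
#' @param sd trait standard deviation
#' @return CV on the percent scale
#' @examples
#' cv_from_moments(66.99, 7.17) # 10.70
#' @export
cv_from_moments <- function(mean, sd) {
  if (any(mean == 0)) stop("CV undefined for zero mean")
  sd / mean * 100
}

# Nearest positive semi-definite repair for user-supplied correlation targets.
#' @keywords internal
nearest_psd_correlation <- function(R, tol = 0.1) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  if (max(abs(R - t(R))) > 1e-8) stop("correlation matrix must be symmetric")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= -1e-10) return(R)
  fixed <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
  delta <- abs(fixed - R)
  if (max(delta) > tol) {
    worst <- which(delta == max(delta), arr.ind = TRUE)[1, ]
    nm <- rownames(R)
    if (is.null(nm)) nm <- as.character(seq_len(nrow(R)))
    stop(sprintf(
      "correlation target not repairable within tolerance %.2f: pair (%s, %s) moved by %.3f",
      tol, nm[worst[1]], nm[worst[2]], max(delta)
    ))
  }
  dimnames(fixed) <- dimnames(R)
  fixed
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
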