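# Core collection selection and evaluation: Gower distances over the trait
# matrix, maximization of the average entry-to-nearest-entry (E-NE) distance
# by seeded multi-restart steepest-ascent swaps, and the CR/VR/VD/MD quality
# statistics comparing the core against the whole collection.

#' Gower distance matrix over a trait matrix
#'
#' d(i, j) = mean over traits of per-trait dissimilarity: |x_i - x_j| / range
#' for numeric traits, 0/1 mismatch for categorical ones; traits missing in
#' either accession are excluded pairwise from the mean. Numeric traits with
#' zero range are dropped with a warning.
#'
#' @param matrix a `trait_matrix` (or data.frame); rows identified by
#'   `accession_id` if present
#' @param traits columns to include (default: the standard trait codes
#'   present; character/factor columns among them are treated as categorical)
#' @return object of class `gower_dist`: the n x n distance matrix `d`
#'   (dimnames = accession ids), the numeric trait ranges used, and the trait
#'   set
#' @export
gower_distances <- function(matrix, traits = trait_columns(matrix)) {
  df <- as.data.frame(matrix)
  n <- nrow(df)
  if (n < 2) stop("need at least two accessions")
  ids <- if (!is.null(df$accession_id)) as.character(df$accession_id)
         else as.character(seq_len(n))

  ranges <- c()
  contrib <- matrix(0, n, n)
  counts <- matrix(0, n, n)
  used <- character(0)
  for (t in traits) {
    x <- df[[t]]
    if (is.numeric(x)) {
      rng <- diff(range(x, na.rm = TRUE))
      if (!is.finite(rng) || rng == 0) {
        warning("trait ", t, " has zero range; dropped from Gower distance")
        next
      }
      ranges[t] <- rng
      dx <- abs(outer(x, x, "-")) / rng
    } else {
      x <- as.character(x)
      dx <- outer(x, x, "!=") * 1
    }
    ok <- !is.na(df[[t]])
    obs <- outer(ok, ok, "&")
    dx[!obs] <- 0
    contrib <- contrib + dx
    counts <- counts + obs
    used <- c(used, t)
  }
  if (length(used) == 0) stop("no usable traits")
  if (any(counts[upper.tri(counts)] == 0)) {
    bad <- which(counts == 0 & upper.tri(counts), arr.ind = TRUE)[1, ]
    stop("accessions ", ids[bad[1]], " and ", ids[bad[2]],
         " share no observed traits")
  }
  d <- contrib / counts
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  structure(list(d = d, ranges = ranges, traits = used),
            class = "gower_dist")
}

# Average entry-to-nearest-entry distance of a selected index set.
#' @keywords internal
.ene_objective <- function(D, sel) {
  Ds <- D[sel, sel, drop = FALSE]
  diag(Ds) <- Inf
  mean(apply(Ds, 1, min))
}

# Greedy maximin (farthest-point) seeding from a given start index.
#' @keywords internal
.greedy_seed <- function(D, k, start) {
  n <- nrow(D)
  sel <- start
  mind <- D[, start]
  while (length(sel) < k) {
    mind[sel] <- -Inf
    nxt <- which.max(mind)
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
  }
  sel
}

# Steepest-ascent single-swap local search; returns list(sel, trace).
#' @keywords internal
.swap_ascent <- function(D, sel, tol = 1e-12) {
  n <- nrow(D)
  k <- length(sel)
  trace <- .ene_objective(D, sel)
  repeat {
    comp <- setdiff(seq_len(n), sel)
    Ds <- D[sel, sel, drop = FALSE]
    diag(Ds) <- Inf
    ord <- apply(Ds, 1, order)[1:2, , drop = FALSE] # two nearest per member
    m1i <- ord[1, ]; m1 <- Ds[cbind(seq_len(k), m1i)]
    m2 <- Ds[cbind(seq_len(k), ord[2, ])]
    best_obj <- trace[length(trace)]
    best_swap <- NULL
    for (e in seq_len(k)) {
      rest <- setdiff(seq_len(k), e)
      # nearest member distance for each remaining member once e is gone
      base <- ifelse(m1i[rest] == e, m2[rest], m1[rest])
      M <- D[sel[rest], comp, drop = FALSE]
      newvals <- pmin(M, base)                 # base recycles down columns
      cand_obj <- (colSums(newvals) + apply(M, 2, min)) / k
      j <- which.max(cand_obj)
      if (cand_obj[j] > best_obj + tol) {
        best_obj <- cand_obj[j]
        best_swap <- c(e, comp[j])
      }
    }
    if (is.null(best_swap)) break
    sel[best_swap[1]] <- best_swap[2]
    trace <- c(trace, best_obj)
  }
  list(sel = sel, trace = trace)
}

#' Select a core collection by E-NE maximization
#'
#' Maximizes the average entry-to-nearest-entry distance
#' E-NE(S) = (1/|S|) sum_e min_{e' != e} d(e, e') over subsets of the
#' requested size, by greedy farthest-point seeding followed by
#' steepest-ascent single-swap local search, with seeded random restarts.
#' The default sampling intensity of 20\% (size = round-half-up of
#' intensity x n) reproduces the conventional core sizing: 203 accessions
#' give a 41-entry core.
#'
#' @param dist a `gower_dist` or a symmetric distance matrix
#' @param size core size; overrides `intensity` when given
#' @param intensity sampling intensity in (0, 1); size = floor(intensity*n + 0.5)
#' @param seed integer seed driving restart starting points
#' @param restarts number of random restarts (the first start is the global
#'   maximin pair; the rest are seeded random entries)
#' @return object of class `core_result`: ids, size, objective, improvement
#'   trace of the winning restart, seed
#' @export
select_core <- function(dist, size = NULL, intensity = 0.2, seed = 1L,
                        restarts = 10) {
  D <- if (inherits(dist, "gower_dist")) dist$d else as.matrix(dist)
  n <- nrow(D)
  ids <- rownames(D) %||% as.character(seq_len(n))
  if (is.null(size)) {
    if (intensity <= 0 || intensity >= 1) stop("intensity must lie in (0, 1)")
    size <- floor(intensity * n + 0.5) # round half-up
  }
  size <- as.integer(size)
  if (size < 2) stop("core size must be at least 2")
  if (size >= n) {
    warning("requested size >= collection size; returning the whole set")
    obj <- .ene_objective(D, seq_len(n))
    return(structure(list(ids = ids, size = n, objective = obj,
                          trace = obj, seed = as.integer(seed)),
                     class = "core_result"))
  }
  set.seed(as.integer(seed))
  starts <- c(which.max(apply(D, 1, max)),
              sample.int(n, max(0, restarts - 1), replace = restarts - 1 > n))
  best <- NULL
  for (s in starts) {
    res <- .swap_ascent(D, .greedy_seed(D, size, s))
    if (is.null(best) || max(res$trace) > best$objective + 1e-15) {
      best <- list(sel = res$sel, objective = max(res$trace), trace = res$trace)
    }
  }
  structure(list(
    ids = ids[sort(best$sel)], size = size, objective = best$objective,
    trace = best$trace, seed = as.integer(seed)
  ), class = "core_result")
}

#' @export
print.core_result <- function(x, ...) {
  cat(sprintf("Core collection: %d entries, E-NE objective = %.5f (%d local-search steps)\n",
              x$size, x$objective, length(x$trace) - 1))
  invisible(x)
}

#' Exhaustive E-NE optimum for small problems
#'
#' Enumerates all subsets of the given size; usable as an oracle for the
#' heuristic search at n <= ~15.
#'
#' @param dist `gower_dist` or distance matrix
#' @param size subset size
#' @return list with objective and ids
#' @export
enumerate_core_optimum <- function(dist, size) {
  D <- if (inherits(dist, "gower_dist")) dist$d else as.matrix(dist)
  n <- nrow(D)
  if (choose(n, size) > 2e6) stop("enumeration too large")
  ids <- rownames(D) %||% as.character(seq_len(n))
  best <- -Inf; best_sel <- NULL
  sets <- utils::combn(n, size)
  for (j in seq_len(ncol(sets))) {
    o <- .ene_objective(D, sets[, j])
    if (o > best) { best <- o; best_sel <- sets[, j] }
  }
  list(objective = best, ids = ids[best_sel])
}

#' @keywords internal
.quality_stats <- function(x) {
  c(range = diff(range(x)), cv = stats::sd(x) / mean(x) * 100,
    var = stats::var(x), mean = mean(x))
}

#' @keywords internal
.assemble_quality <- function(per_trait) {
  aggregates <- c(
    CR = mean(per_trait$CR, na.rm = TRUE),
    VR = mean(per_trait$VR, na.rm = TRUE),
    VD = mean(per_trait$VD, na.rm = TRUE),
    MD = mean(per_trait$MD, na.rm = TRUE)
  )
  structure(list(per_trait = per_trait, aggregates = aggregates),
            class = "core_quality")
}

#' Core-quality statistics from raw data
#'
#' Per trait i (over the m evaluated traits), with W the whole and C the core
#' collection: CR_i = R_C/R_W x 100 (range coincidence),
#' VR_i = CV_C/CV_W x 100 (variable rate), VD_i = |V_W - V_C|/V_C x 100
#' (variance difference), MD_i = |M_W - M_C|/M_C x 100 (mean difference);
#' aggregates are arithmetic means over traits. Sample (n - 1) variance and
#' SD throughout. Core-side denominators are used exactly as the statistics
#' are defined. A core equal to the whole collection is the fixed point
#' (CR = VR = 100, VD = MD = 0). Traits constant in the core make VD/MD
#' denominators degenerate and are flagged NA with a warning.
#'
#' @param whole a `trait_matrix` of the whole collection
#' @param core_ids accession ids of the core (subset of the whole)
#' @param traits trait columns to evaluate
#' @return object of class `core_quality` with per-trait statistics and the
#'   four aggregates
#' @export
evaluate_core <- function(whole, core_ids, traits = trait_columns(whole)) {
  ids <- whole$accession_id
  if (!all(core_ids %in% ids)) stop("core ids must be a subset of the whole")
  if (length(core_ids) < 2) stop("core must hold at least two accessions")
  in_core <- ids %in% core_ids
  rows <- lapply(traits, function(t) {
    xw <- whole[[t]][!is.na(whole[[t]])]
    xc <- whole[[t]][in_core & !is.na(whole[[t]])]
    if (length(xc) < 2) {
      warning("trait ", t, " has fewer than two core values; skipped")
      return(NULL)
    }
    sw <- .quality_stats(xw); sc <- .quality_stats(xc)
    degenerate <- sc[["var"]] == 0
    if (degenerate) warning("trait ", t, " constant in core; VR/VD flagged NA")
    data.frame(
      trait = t,
      range_whole = sw[["range"]], range_core = sc[["range"]],
      CR = sc[["range"]] / sw[["range"]] * 100,
      cv_whole = sw[["cv"]], cv_core = sc[["cv"]],
      VR = if (degenerate) NA_real_ else sc[["cv"]] / sw[["cv"]] * 100,
      var_whole = sw[["var"]], var_core = sc[["var"]],
      VD = if (degenerate) NA_real_ else
        abs(sw[["var"]] - sc[["var"]]) / sc[["var"]] * 100,
      mean_whole = sw[["mean"]], mean_core = sc[["mean"]],
      MD = abs(sw[["mean"]] - sc[["mean"]]) / sc[["mean"]] * 100,
      stringsAsFactors = FALSE
    )
  })
  .assemble_quality(do.call(rbind, rows))
}

#' Core-quality statistics from published summary cells
#'
#' Computes the same CR/VR/VD/MD statistics as [evaluate_core()] but from
#' per-trait summary values (ranges, CVs, means, optionally variances) of the
#' whole and core collections, e.g. as printed in a published quality table.
#' When variance columns are absent they are derived as (cv/100 x mean)^2.
#'
#' @param summary data.frame with columns trait, range_whole, range_core,
#'   cv_whole, cv_core, mean_whole, mean_core and optionally var_whole,
#'   var_core
#' @return object of class `core_quality`
#' @export
core_quality_from_summary <- function(summary) {
  need <- c("trait", "range_whole", "range_core", "cv_whole", "cv_core",
            "mean_whole", "mean_core")
  if (!all(need %in% names(summary))) {
    stop("summary must have columns: ", paste(need, collapse = ", "))
  }
  s <- summary
  if (is.null(s$var_whole)) s$var_whole <- (s$cv_whole / 100 * s$mean_whole)^2
  if (is.null(s$var_core)) s$var_core <- (s$cv_core / 100 * s$mean_core)^2
  per_trait <- data.frame(
    trait = s$trait,
    range_whole = s$range_whole, range_core = s$range_core,
    CR = s$range_core / s$range_whole * 100,
    cv_whole = s$cv_whole, cv_core = s$cv_core,
    VR = s$cv_core / s$cv_whole * 100,
    var_whole = s$var_whole, var_core = s$var_core,
    VD = abs(s$var_whole - s$var_core) / s$var_core * 100,
    mean_whole = s$mean_whole, mean_core = s$mean_core,
    MD = abs(s$mean_whole - s$mean_core) / s$mean_core * 100,
    stringsAsFactors = FALSE
  )
  .assemble_quality(per_trait)
}

#' @export
print.core_quality <- function(x, digits = 2, ...) {
  cat("Core-quality statistics (aggregates over",
      nrow(x$per_trait), "traits):\n")
  print(round(x$aggregates, digits))
  invisible(x)
}

#' Whole-vs-core trait comparisons
#'
#' Per trait, a two-sample comparison of the whole collection against the
#' core (Welch t or Mann-Whitney U by the same normality gate as
#' [group_effect()]); the edible ratio is compared on the logit scale, the
#' documented stand-in for a quasi-binomial model. A well-chosen core should
#' leave every trait non-significant.
#'
#' @param whole a `trait_matrix`
#' @param core_ids core accession ids
#' @param traits traits to compare
#' @param method_policy "auto", "parametric" or "nonparametric"
#' @return data.frame with trait, method, statistic, p_value
#' @export
compare_whole_core <- function(whole, core_ids,
                               traits = trait_columns(whole),
                               method_policy = "auto") {
  in_core <- whole$accession_id %in% core_ids
  rows <- lapply(traits, function(t) {
    x <- whole[[t]]
    if (identical(t, "EdRt")) {
      x <- logit(pmin(pmax(x / 100, 1e-6), 1 - 1e-6))
    }
    xw <- x[!is.na(x)]
    xc <- x[in_core & !is.na(x)]
    if (length(unique(xc)) < 2 || length(unique(xw)) < 2) {
      warning("trait ", t, " degenerate; comparison skipped")
      return(data.frame(trait = t, method = "skipped",
                        statistic = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    parametric <- switch(method_policy,
      parametric = TRUE, nonparametric = FALSE,
      auto = .normality_ok(xw) && .normality_ok(xc)
    )
    if (parametric) {
      ht <- stats::t.test(xw, xc); method <- "welch_t"
    } else {
      ht <- suppressWarnings(stats::wilcox.test(xw, xc)); method <- "mann_whitney_u"
    }
    data.frame(trait = t, method = method, statistic = unname(ht$statistic),
               p_value = ht$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
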