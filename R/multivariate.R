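# PCA on the trait correlation matrix, component retention, Ward clustering
# on retained component scores (with k chosen by the inertia-gain jump and an
# optional k-means consolidation pass), v-test cluster characterization and a
# cluster-by-factor chi-square.

#' Principal component analysis of a trait matrix
#'
#' Eigen-decomposition of the correlation matrix (default) or covariance
#' matrix of complete cases. Deterministic sign convention: each loading
#' vector is oriented so its largest-magnitude entry is positive.
#'
#' @param matrix a `trait_matrix` or numeric data.frame/matrix
#' @param traits columns to use (defaults to the standard trait codes present)
#' @param standardize work on the correlation matrix (TRUE) or covariance
#' @return object of class `pca_model`: loadings (trait x component),
#'   explained variance fractions, scores (accession x component), sdev
#' @export
trait_pca <- function(matrix, traits = trait_columns(matrix),
                      standardize = TRUE) {
  X <- as.matrix(as.data.frame(matrix)[, traits, drop = FALSE])
  storage.mode(X) <- "double"
  cc <- stats::complete.cases(X)
  X <- X[cc, , drop = FALSE]
  if (nrow(X) <= ncol(X)) stop("need more complete rows than traits")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant trait(s): ", paste(traits[sds == 0], collapse = ", "))
  }
  Xc <- scale(X, center = TRUE, scale = standardize)
  S <- crossprod(Xc) / (nrow(Xc) - 1)
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  dimnames(vecs) <- list(traits, paste0("PC", seq_along(vals)))
  scores <- Xc %*% vecs
  rn <- if (!is.null(matrix$accession_id)) matrix$accession_id[cc] else which(cc)
  rownames(scores) <- rn
  structure(list(
    loadings = vecs,
    explained = vals / sum(vals),
    sdev = sqrt(vals),
    scores = scores,
    standardize = standardize,
    complete_rows = rn
  ), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA model:", ncol(x$loadings), "components\n")
  cat("explained fractions:",
      paste(sprintf("%.3f", x$explained), collapse = " "), "\n")
  invisible(x)
}

#' Choose how many principal components to retain
#'
#' Policies: `"cumulative"` keeps the smallest k whose cumulative explained
#' fraction reaches `tau` (default 0.80, which retains four components on data
#' shaped like the reference collection); `"kaiser"` keeps components with
#' eigenvalue > 1 on the correlation scale; `"fixed"` returns `k` as given.
#'
#' @param model a `pca_model`
#' @param policy retention rule
#' @param tau cumulative-fraction threshold in (0, 1]
#' @param k fixed number of components for `policy = "fixed"`
#' @return integer number of components
#' @export
retain_components <- function(model, policy = c("cumulative", "kaiser", "fixed"),
                              tau = 0.80, k = NULL) {
  policy <- match.arg(policy)
  switch(policy,
    cumulative = {
      if (tau <= 0 || tau > 1) stop("tau must lie in (0, 1]")
      unname(which(cumsum(model$explained) >= tau - 1e-12)[1])
    },
    kaiser = max(1L, sum(model$sdev^2 > 1)),
    fixed = {
      if (is.null(k)) stop("policy 'fixed' needs k")
      as.integer(k)
    }
  )
}

#' @keywords internal
.within_inertia <- function(X, cl) {
  sum(vapply(split(seq_len(nrow(X)), cl), function(i) {
    Xi <- X[i, , drop = FALSE]
    sum(sweep(Xi, 2, colMeans(Xi))^2)
  }, 0))
}

#' Hierarchical clustering on retained component scores
#'
#' Ward-linkage agglomeration (on Euclidean distances of the retained
#' component scores), with the number of clusters chosen in 2..k_max by the
#' largest relative jump of between-cut within-cluster inertia gains -- the
#' usual HCPC heuristic -- unless `k_policy = "fixed"`. An optional seeded
#' k-means consolidation pass (10 iterations, started from the hierarchical
#' cluster centroids) polishes the assignment.
#'
#' @param scores numeric matrix of retained component scores (rows named by
#'   accession), or a `pca_model` plus `n_components`
#' @param k_policy "auto" (inertia-gain jump) or "fixed"
#' @param k cluster count when `k_policy = "fixed"`
#' @param k_max largest k searched under "auto"
#' @param consolidate run the k-means consolidation pass
#' @param seed seed for the consolidation pass
#' @param n_components when `scores` is a `pca_model`, how many leading
#'   components to use (default: [retain_components()] with defaults)
#' @return object of class `cluster_solution`: assignment (named integer
#'   vector), k, merge-height profile, the hclust tree, within-cluster inertia
#' @export
cluster_accessions <- function(scores, k_policy = c("auto", "fixed"), k = NULL,
                               k_max = 10, consolidate = TRUE, seed = 1L,
                               n_components = NULL) {
  k_policy <- match.arg(k_policy)
  if (inherits(scores, "pca_model")) {
    nc <- n_components %||% retain_components(scores)
    scores <- scores$scores[, seq_len(nc), drop = FALSE]
  }
  X <- as.matrix(scores)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 rows to cluster")
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")

  k_max <- min(k_max, n - 1)
  if (k_policy == "fixed") {
    if (is.null(k)) stop("k_policy 'fixed' needs k")
    k_use <- as.integer(k)
  } else {
    W <- vapply(1:(k_max + 1), function(kk) {
      .within_inertia(X, stats::cutree(hc, kk))
    }, 0)
    gains <- W[-length(W)] - W[-1] # gain of moving from k to k+1 clusters
    ratio <- gains[-length(gains)] / pmax(gains[-1], 1e-300)
    # ratio[m] compares the gain achieved by the cut at k = m+1 with the next
    k_use <- which.max(ratio) + 1L
  }
  cl <- stats::cutree(hc, k_use)
  if (consolidate && k_use >= 2 && k_use < n) {
    centers <- do.call(rbind, lapply(split(seq_len(n), cl), function(i) {
      colMeans(X[i, , drop = FALSE])
    }))
    set.seed(as.integer(seed))
    km <- suppressWarnings(stats::kmeans(X, centers = centers, iter.max = 10))
    if (length(unique(km$cluster)) == k_use) cl <- km$cluster
  }
  names(cl) <- rownames(X)
  structure(list(
    assignment = cl, k = k_use, heights = hc$height, tree = hc,
    within_inertia = .within_inertia(X, cl)
  ), class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("Cluster solution: k = %d, sizes: %s\n", x$k,
              paste(table(x$assignment), collapse = ", ")))
  invisible(x)
}

#' Characterize clusters by standardized mean comparisons (v-tests)
#'
#' For cluster k and trait with overall mean xbar, overall (population)
#' variance s2, cluster mean xbar_k and size n_k out of N:
#' v = (xbar_k - xbar) / sqrt(((N - n_k) / (N - 1)) * s2 / n_k).
#' Traits with |v| >= `threshold` (default 1.96) flag the cluster as
#' "greater" or "lower" than the collection average; otherwise the trait does
#' not characterize the cluster.
#'
#' @param matrix a `trait_matrix`
#' @param assignment named cluster vector (accession_id -> cluster) or a
#'   `cluster_solution`
#' @param traits trait columns to profile
#' @param threshold |v| cutoff for flagging
#' @return data.frame with cluster, trait, cluster_mean, overall_mean,
#'   v_statistic, flag
#' @export
characterize_clusters <- function(matrix, assignment,
                                  traits = trait_columns(matrix),
                                  threshold = 1.96) {
  if (inherits(assignment, "cluster_solution")) assignment <- assignment$assignment
  idx <- match(names(assignment), matrix$accession_id)
  if (!is.null(names(assignment)) && !anyNA(idx)) {
    matrix <- matrix[idx, , drop = FALSE]
  } else if (length(assignment) != nrow(matrix)) {
    stop("assignment must be named by accession_id or match matrix rows")
  }
  cl <- as.integer(as.factor(assignment))
  N <- length(cl)
  rows <- list()
  for (t in traits) {
    x <- matrix[[t]]
    ok <- !is.na(x)
    xx <- x[ok]; cc <- cl[ok]; Nt <- length(xx)
    xbar <- mean(xx)
    s2 <- sum((xx - xbar)^2) / Nt # population variance, v-test convention
    for (kk in sort(unique(cc))) {
      nk <- sum(cc == kk)
      mk <- mean(xx[cc == kk])
      v <- if (nk == Nt || s2 == 0) 0 else {
        (mk - xbar) / sqrt(((Nt - nk) / (Nt - 1)) * s2 / nk)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = kk, trait = t, cluster_mean = mk, overall_mean = xbar,
        v_statistic = v,
        flag = if (v >= threshold) "greater"
               else if (v <= -threshold) "lower" else "ns",
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Chi-square association between clusters and a factor
#'
#' Pearson chi-square (no continuity correction) on the cluster x factor
#' contingency table, warning when any expected count falls below 5.
#'
#' @param assignment cluster labels (vector or `cluster_solution`)
#' @param factor_labels factor labels aligned with the assignment
#' @return list with statistic, df, p_value and the table
#' @export
cluster_factor_association <- function(assignment, factor_labels) {
  if (inherits(assignment, "cluster_solution")) assignment <- assignment$assignment
  tab <- table(cluster = assignment, factor = factor_labels)
  if (any(dim(tab) < 2)) stop("need >= 2 clusters and >= 2 factor levels")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    warning("expected counts below 5; chi-square approximation is rough")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, table = tab)
}
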