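#' Connectome container
#'
#' A labelled symmetric matrix over brain regions with a `kind` tag:
#' `"covariance"`, `"precision"`, or `"normalized_precision"` (inverse
#' covariance rescaled to unit diagonal, whose negated off-diagonals are
#' partial correlations).
#'
#' @param matrix symmetric numeric matrix.
#' @param labels region names (default from dimnames).
#' @param kind one of `"covariance"`, `"precision"`,
#'   `"normalized_precision"`.
#' @param shrinkage_lambda shrinkage intensity used to produce the
#'   underlying covariance, if any (provenance).
#' @return An object of class `connectome`.
#' @export
connectome <- function(matrix, labels = rownames(matrix),
                       kind = c("covariance", "precision",
                                "normalized_precision"),
                       shrinkage_lambda = NA_real_) {
  kind <- match.arg(kind)
  assert_symmetric(matrix, tol = 1e-8, arg = "matrix")
  if (is.null(labels)) labels <- sprintf("R%02d", seq_len(nrow(matrix)))
  if (length(labels) != nrow(matrix)) {
    abort("`labels` length must match the matrix order.")
  }
  dimnames(matrix) <- list(labels, labels)
  if (kind == "normalized_precision" &&
      max(abs(diag(matrix) - 1)) > 1e-8) {
    abort("A normalized_precision connectome must have unit diagonal.")
  }
  structure(list(matrix = symmetrize(matrix), labels = labels, kind = kind,
                 shrinkage_lambda = shrinkage_lambda),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %s, %d regions", x$kind, nrow(x$matrix)))
  if (!is.na(x$shrinkage_lambda)) {
    cat(sprintf(", lambda = %.4f", x$shrinkage_lambda))
  }
  cat("\n")
  invisible(x)
}

as_conn_matrix <- function(x) {
  if (inherits(x, "connectome")) x$matrix else as.matrix(x)
}

# Analytic Ledoit-Wolf shrinkage intensity toward the identity target:
# lambda* = sum_ij Var-hat(S_ij) / sum_ij (S_ij - I_ij)^2, with the
# variance of each covariance entry estimated from the per-sample
# centered outer products, then clipped to [0, 1].
ledoit_wolf_lambda <- function(Xc, S) {
  Tn <- nrow(Xc)
  num <- 0
  # Var(s_ij) ~= T / (T-1)^3 * sum_t (w_tij - mean_t w_tij)^2, w_tij = x_ti x_tj
  # accumulated without materializing the T x p^2 array.
  W_mean <- crossprod(Xc) / Tn
  sq_sum <- crossprod(Xc^2)              # sum_t x_ti^2 x_tj^2
  ss <- sq_sum - Tn * W_mean^2           # sum_t (w_tij - wbar_ij)^2
  num <- sum(ss) * Tn / (Tn - 1)^3
  den <- sum((S - diag(nrow(S)))^2)
  if (den <= 0) return(1)
  min(max(num / den, 0), 1)
}

#' Ledoit-Wolf shrinkage covariance estimate
#'
#' Computes the well-conditioned covariance estimate
#' \deqn{\hat\Sigma_\lambda = \lambda I + (1 - \lambda)\hat\Sigma,}
#' a convex combination of the identity target and the sample covariance
#' of the column-centered data, with the shrinkage intensity
#' \eqn{\lambda \in [0, 1]} obtained from the closed-form Ledoit-Wolf
#' estimator for the identity target. The result is symmetric positive
#' definite even when the number of time samples is below the number of
#' regions, which is what makes the subsequent precision (partial
#' correlation) step feasible for connectomes.
#'
#' @param ts a [region_ts()] or a time-by-regions numeric matrix with at
#'   least 2 rows.
#' @param lambda optional fixed shrinkage intensity in \[0, 1\];
#'   overrides the analytic value (e.g. `lambda = 1` returns the
#'   identity).
#' @return A [connectome()] of kind `"covariance"` with
#'   `shrinkage_lambda` recorded.
#' @export
shrinkage_covariance <- function(ts, lambda = NULL) {
  X <- as_region_values(ts)
  if (nrow(X) < 2) abort("Need at least 2 time samples.")
  labels <- colnames(X)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / (nrow(X) - 1)
  lam <- if (is.null(lambda)) ledoit_wolf_lambda(Xc, S) else {
    if (lambda < 0 || lambda > 1) abort("`lambda` must lie in [0, 1].")
    lambda
  }
  Sl <- symmetrize(lam * diag(ncol(X)) + (1 - lam) * S)
  if (!check_spd(Sl, tol = 0)$spd) {
    # Degenerate all-constant input can leave a zero eigenvalue; pull fully
    # to the identity as lambda -> 1 would.
    Sl <- symmetrize(diag(ncol(X)))
    lam <- 1
  }
  connectome(Sl, labels = labels, kind = "covariance", shrinkage_lambda = lam)
}

#' Normalized precision (partial-correlation structure)
#'
#' Inverts an SPD covariance and rescales the inverse to unit diagonal:
#' \eqn{Dg^{-1/2} \Sigma^{-1} Dg^{-1/2}} with \eqn{Dg} the diagonal of
#' the precision matrix. The negated off-diagonals of this matrix are the
#' partial correlations between region pairs given all other regions.
#'
#' @param cov a [connectome()] of kind `"covariance"` (or an SPD matrix).
#' @return A [connectome()] of kind `"normalized_precision"`.
#' @export
normalized_precision <- function(cov) {
  M <- as_conn_matrix(cov)
  assert_symmetric(M, arg = "cov")
  chk <- check_spd(M)
  if (!chk$spd) {
    abort(sprintf("Covariance is not SPD (min eigenvalue %g).",
                  chk$min_eigenvalue))
  }
  P <- symmetrize(chol2inv(chol(M)))
  d <- 1 / sqrt(diag(P))
  N <- symmetrize(P * tcrossprod(d))
  diag(N) <- 1
  lam <- if (inherits(cov, "connectome")) cov$shrinkage_lambda else NA_real_
  connectome(N, labels = rownames(M) %||% NULL, kind = "normalized_precision",
             shrinkage_lambda = lam)
}

#' Partial-correlation matrix
#'
#' Negates the off-diagonal entries of a normalized precision matrix (and
#' sets the diagonal to 1), yielding the matrix of partial correlations:
#' the connectivity strength between two regions once the influence of
#' all others has been regressed out.
#'
#' @param np a [connectome()] of kind `"normalized_precision"`.
#' @return A symmetric numeric matrix with unit diagonal.
#' @export
partial_correlation <- function(np) {
  if (!inherits(np, "connectome") || np$kind != "normalized_precision") {
    abort("`np` must be a normalized_precision connectome.")
  }
  P <- -np$matrix
  diag(P) <- 1
  P
}

#' Vectorize and devectorize connectome edges
#'
#' `vectorize_edges()` extracts the strict upper triangle (i < j,
#' row-major) of a unit-diagonal symmetric matrix; `devectorize_edges()`
#' rebuilds the matrix. The diagonal is excluded because it is identically
#' one for normalized precisions. The pair is an exact round trip.
#'
#' @param np a [connectome()] or symmetric matrix.
#' @return `vectorize_edges()`: a named numeric vector of length
#'   `R(R-1)/2`; `devectorize_edges()`: a symmetric unit-diagonal matrix.
#' @export
vectorize_edges <- function(np) {
  M <- as_conn_matrix(np)
  assert_symmetric(M, arg = "np")
  idx <- edge_index_pairs(rownames(M) %||% sprintf("R%02d", seq_len(nrow(M))))
  v <- t(M)[lower.tri(M)]     # row-major upper triangle
  names(v) <- paste(idx$region_i, idx$region_j, sep = "--")
  v
}

#' @rdname vectorize_edges
#' @param edges numeric vector of length `R(R-1)/2`.
#' @param labels region labels defining the matrix order `R`.
#' @export
devectorize_edges <- function(edges, labels) {
  R <- length(labels)
  if (length(edges) != R * (R - 1) / 2) {
    abort(sprintf("Expected %d edges for %d regions, got %d.",
                  R * (R - 1) / 2, R, length(edges)))
  }
  M <- diag(R)
  M[lower.tri(M)] <- 0
  Mt <- t(M)
  Mt[lower.tri(Mt)] <- edges   # fill row-major upper triangle
  M <- t(Mt)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  dimnames(M) <- list(labels, labels)
  M
}

# Ordered (i < j) region pairs in row-major upper-triangle order.
edge_index_pairs <- function(labels) {
  R <- length(labels)
  i <- rep(seq_len(R - 1), times = (R - 1):1)
  j <- unlist(lapply(seq_len(R - 1), function(k) (k + 1):R))
  tibble(edge = seq_along(i), region_i = labels[i], region_j = labels[j])
}

#' Strongest connections by absolute weight
#'
#' Ranks the edges of a symmetric matrix by absolute weight and returns
#' the top `ceiling(fraction * n_edges)` as a tibble with a sign flag,
#' the convention used when displaying the strongest partial correlations
#' of a group-average connectome. Ties at the cutoff are broken by edge
#' index (row-major upper-triangle order).
#'
#' @param matrix symmetric matrix (or [connectome()]).
#' @param fraction fraction of edges to keep, in (0, 1\].
#' @return A tibble with `region_i`, `region_j`, `weight`, `sign`
#'   (`"positive"`/`"negative"`), ordered by decreasing absolute weight.
#' @export
threshold_top_fraction <- function(matrix, fraction) {
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1].")
  M <- as_conn_matrix(matrix)
  v <- vectorize_edges(M)
  idx <- edge_index_pairs(rownames(as_conn_matrix(matrix)) %||%
                            sprintf("R%02d", seq_len(nrow(M))))
  k <- ceiling(fraction * length(v))
  ord <- order(-abs(v), idx$edge)
  top <- ord[seq_len(k)]
  tibble(region_i = idx$region_i[top], region_j = idx$region_j[top],
         weight = unname(v[top]),
         sign = unname(ifelse(v[top] >= 0, "positive", "negative")))
}

#' Element-wise group average of connectomes
#'
#' @param connectomes list of [connectome()] objects with identical labels
#'   and kind.
#' @return A [connectome()] of the same kind holding the element-wise
#'   mean.
#' @export
group_average_connectome <- function(connectomes) {
  stopifnot(length(connectomes) >= 1)
  mats <- lapply(connectomes, as_conn_matrix)
  labs <- connectomes[[1]]$labels
  M <- Reduce(`+`, mats) / length(mats)
  kind <- connectomes[[1]]$kind
  if (kind == "normalized_precision") diag(M) <- 1
  connectome(M, labels = labs, kind = kind)
}

#' Build an edge dataset from per-subject connectomes
#'
#' Stacks the vectorized upper-triangle edges of each subject's
#' normalized precision into a subjects-by-edges matrix, the canonical
#' variable consumed by the sparse CCA.
#'
#' @param connectomes list of [connectome()] objects (one per subject)
#'   with identical labels.
#' @param band,modality optional tags.
#' @return An [edge_dataset()].
#' @export
edge_dataset_from_connectomes <- function(connectomes, band = NULL,
                                          modality = NULL) {
  labs <- connectomes[[1]]$labels
  rows <- lapply(connectomes, function(cn) {
    if (!identical(cn$labels, labs)) abort("Connectome labels differ across subjects.")
    vectorize_edges(cn)
  })
  edge_dataset(do.call(rbind, rows), edge_index = edge_index_pairs(labs),
               band = band, modality = modality, labels = labs)
}

#' Edge dataset container
#'
#' A subjects-by-edges numeric matrix, optionally with an edge index
#' naming the region pair behind each column.
#'
#' @param matrix numeric matrix, subjects in rows, edges in columns.
#' @param edge_index optional tibble with columns `edge`, `region_i`,
#'   `region_j` of length `ncol(matrix)`.
#' @param band,modality optional tags.
#' @param labels region labels (enables devectorization of rows).
#' @return An object of class `edge_dataset`.
#' @export
edge_dataset <- function(matrix, edge_index = NULL, band = NULL,
                         modality = NULL, labels = NULL) {
  matrix <- as.matrix(matrix)
  if (!is.numeric(matrix)) abort("`matrix` must be numeric.")
  if (!is.null(edge_index) && nrow(edge_index) != ncol(matrix)) {
    abort("`edge_index` must have one row per edge column.")
  }
  structure(list(matrix = matrix, edge_index = edge_index, band = band,
                 modality = modality, labels = labels),
            class = "edge_dataset")
}

#' @export
print.edge_dataset <- function(x, ...) {
  cat(sprintf("<edge_dataset> %d subjects x %d edges", nrow(x$matrix),
              ncol(x$matrix)))
  if (!is.null(x$band)) cat(sprintf("  band=%s", x$band))
  if (!is.null(x$modality)) cat(sprintf("  modality=%s", x$modality))
  cat("\n")
  invisible(x)
}

#' @export
dim.edge_dataset <- function(x) dim(x$matrix)

as_edge_matrix <- function(x) {
  if (inherits(x, "edge_dataset")) x$matrix else as.matrix(x)
}
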