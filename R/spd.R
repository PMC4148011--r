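#' Affine-invariant geodesic distance between SPD matrices
#'
#' Computes the geodesic distance between two symmetric positive-definite
#' (SPD) matrices under the affine-invariant Riemannian metric,
#' \deqn{d_{AI}(P, G) = \sqrt{\sum_i \log^2 \lambda_i},}
#' where \eqn{\lambda_i} are the (generalized) eigenvalues of
#' \eqn{G^{-1}P}, equivalently of \eqn{G^{-1/2} P G^{-1/2}}. This metric is
#' the natural one for covariance and precision matrices: it is invariant
#' to joint affine transformations of both arguments and to matrix
#' inversion, properties the Frobenius norm lacks.
#'
#' The implementation uses the eigenvalue route via a Cholesky whitening of
#' `G` rather than explicit matrix square roots, which is numerically
#' stabler and cheaper; equality with the direct matrix-logarithm
#' evaluation is part of the test suite.
#'
#' @param P,G symmetric positive-definite matrices of the same order.
#' @param tol positive-definiteness tolerance on the minimum eigenvalue.
#' @return A non-negative scalar distance; zero iff `P == G`.
#' @seealso [normalized_dai()] for the matrix-order-normalized variant,
#'   [check_spd()], [repair_spd()].
#' @examples
#' dai(diag(c(exp(2), 1)), diag(2)) # = 2
#' @export
dai <- function(P, G, tol = 1e-12) {
  assert_symmetric(P, arg = "P")
  assert_symmetric(G, arg = "G")
  if (nrow(P) != nrow(G)) {
    abort(sprintf("Order mismatch: P is %d x %d, G is %d x %d.",
                  nrow(P), ncol(P), nrow(G), ncol(G)))
  }
  for (nm in c("P", "G")) {
    M <- if (nm == "P") P else G
    chk <- check_spd(M, tol = tol)
    if (!chk$spd) {
      abort(sprintf("`%s` is not SPD: minimum eigenvalue %g.", nm, chk$min_eigenvalue))
    }
  }
  U <- chol(symmetrize(G))            # G = U'U, upper-triangular U
  A <- forwardsolve(t(U), symmetrize(P))
  W <- t(forwardsolve(t(U), t(A)))
  # W = U^{-T} P U^{-1} is similar to G^{-1}P and symmetric
  ev <- eigen(symmetrize(W), symmetric = TRUE, only.values = TRUE)$values
  sqrt(sum(log(ev)^2))
}

#' Check a symmetric matrix for positive definiteness
#'
#' @param M symmetric matrix.
#' @param tol strict lower bound the minimum eigenvalue must exceed.
#' @return A list with `spd` (logical) and `min_eigenvalue`.
#' @export
check_spd <- function(M, tol = 1e-12) {
  assert_symmetric(M, arg = "M")
  mev <- min(eigen(symmetrize(M), symmetric = TRUE, only.values = TRUE)$values)
  list(spd = mev > tol, min_eigenvalue = mev)
}

#' Repair a symmetric matrix to be positive definite
#'
#' Raises every eigenvalue below `floor` to `floor` and reassembles the
#' matrix. SPD inputs pass through bitwise unchanged. The returned flag
#' records whether a repair occurred, so callers can count repairs (the
#' cross-modal prediction pipeline reports these counts rather than
#' silently discarding failures).
#'
#' @param M symmetric matrix.
#' @param floor eigenvalue floor; default `1e-6` times the largest
#'   eigenvalue of `M` (or `1e-6` if that is not positive).
#' @return A list with `matrix` (SPD) and `repaired` (logical).
#' @export
repair_spd <- function(M, floor = NULL) {
  assert_symmetric(M, arg = "M")
  e <- eigen(symmetrize(M), symmetric = TRUE)
  if (is.null(floor)) {
    top <- max(e$values)
    floor <- if (top > 0) 1e-6 * top else 1e-6
  }
  if (min(e$values) >= floor) {
    return(list(matrix = M, repaired = FALSE))
  }
  vals <- pmax(e$values, floor)
  R <- symmetrize(e$vectors %*% (vals * t(e$vectors)))
  dimnames(R) <- dimnames(M)
  list(matrix = R, repaired = TRUE)
}

#' Calibrate the scaling of the affine-invariant distance with matrix order
#'
#' The expected distance between two independent random SPD matrices grows
#' with the matrix order, so raw distances between connectomes of
#' different sizes (e.g. cortical 68-region vs cortico-subcortical
#' 82-region) are not comparable. This calibration draws `n_pairs` pairs
#' of Wishart matrices at each order, records the median pairwise
#' distance, and fits a least-squares line of median distance against
#' order. Dividing a distance by the fitted line's value at the matrix
#' order (see [normalized_dai()]) makes distances comparable across
#' orders; because the fit is close to linear through small intercepts
#' this is approximately equivalent to dividing by the number of regions.
#'
#' @param orders integer vector of at least 3 distinct matrix orders.
#' @param n_pairs number of Wishart pairs per order.
#' @param dof_rule function mapping an order to the Wishart degrees of
#'   freedom; default twice the order (the minimal dof equal to the order
#'   yields near-singular draws and unstable medians).
#' @param seed integer seed for the Wishart draws.
#' @return An object of class `order_calibration` with fields `slope`,
#'   `intercept`, `fit_r2`, `orders`, `medians`, `dof_rule_label`,
#'   `n_pairs`, `seed`. [tidy()] returns the per-order medians and
#'   [glance()] the fit summary.
#' @export
calibrate_order_normalization <- function(orders, n_pairs = 100,
                                          dof_rule = function(r) 2L * r,
                                          seed = 1L) {
  orders <- sort(unique(as.integer(orders)))
  if (length(orders) < 3) {
    abort("Need at least 3 distinct orders to fit a calibration line.")
  }
  seeds <- derive_seeds(seed, length(orders))
  medians <- vapply(seq_along(orders), function(i) {
    r <- orders[i]
    pairs <- make_wishart_pairs(order = r, dof = dof_rule(r),
                                n_pairs = n_pairs, seed = seeds[i])
    median(vapply(pairs, function(pr) dai(pr[[1]], pr[[2]]), numeric(1)))
  }, numeric(1))
  fit <- lm(medians ~ orders)
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      fit_r2 = summary(fit)$r.squared,
      orders = orders,
      medians = medians,
      n_pairs = n_pairs,
      dof_rule_label = paste(deparse(body(dof_rule)), collapse = " "),
      seed = seed
    ),
    class = "order_calibration"
  )
}

#' Order-normalized affine-invariant distance
#'
#' Divides [dai()] by the calibrated median distance at the matrices'
#' order, so that distances between connectomes with different region
#' counts live on a common scale.
#'
#' @inheritParams dai
#' @param calibration an [calibrate_order_normalization()] result.
#' @return Normalized distance (non-negative scalar).
#' @export
normalized_dai <- function(P, G, calibration) {
  stopifnot(inherits(calibration, "order_calibration"))
  r <- nrow(P)
  rng <- range(calibration$orders)
  if (r < rng[1] || r > rng[2]) {
    warn(sprintf(
      "Matrix order %d outside calibration range [%d, %d]; extrapolating.",
      r, rng[1], rng[2]))
  }
  divisor <- calibration$slope * r + calibration$intercept
  if (divisor <= 0) abort("Calibration line non-positive at this order.")
  dai(P, G) / divisor
}

#' @export
print.order_calibration <- function(x, ...) {
  cat("Order calibration of the affine-invariant distance\n")
  cat(sprintf("  orders: %s (n_pairs = %d per order)\n",
              paste(range(x$orders), collapse = "-"), x$n_pairs))
  cat(sprintf("  median dai ~ %.4f * order + %.4f  (R^2 = %.4f)\n",
              x$slope, x$intercept, x$fit_r2))
  invisible(x)
}

#' Save or load an order calibration as structured text
#'
#' @param calibration an `order_calibration` object.
#' @param path file path (JSON).
#' @return `write_order_calibration()` returns `path` invisibly;
#'   `read_order_calibration()` returns the calibration object.
#' @export
write_order_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "order_calibration"))
  jsonlite::write_json(unclass(calibration), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_order_calibration
#' @export
read_order_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$orders <- as.integer(x$orders)
  structure(x, class = "order_calibration")
}
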