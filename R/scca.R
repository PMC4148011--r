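#' Soft-thresholding operator
#'
#' \eqn{S(a, \delta)_j = sign(a_j) \max(|a_j| - \delta, 0)}, the proximal
#' operator of the L1 penalty and the mechanism producing sparse canonical
#' vectors.
#'
#' @param a numeric vector.
#' @param delta threshold, >= 0.
#' @return Numeric vector of the same length.
#' @export
soft_threshold <- function(a, delta) {
  if (delta < 0) abort("`delta` must be non-negative.")
  sign(a) * pmax(abs(a) - delta, 0)
}

# Solve argmax_u  a'u  s.t. ||u||_2 <= 1, ||u||_1 <= c via the closed form
# u = S(a, delta) / ||S(a, delta)||_2 with delta = 0 if the unconstrained
# solution is feasible, else chosen so the L1 constraint binds. The L1/L2
# ratio of the thresholded vector is continuous and non-increasing in
# delta, so the binding threshold lies in a unique segment between
# consecutive order statistics of |a|, where it solves a quadratic;
# bisection is the fallback when the closed form is numerically unusable.
l1_constrained_direction <- function(a, c, tol = 1e-8) {
  if (all(a == 0)) return(list(u = a, delta = 0))
  u0 <- a / sqrt(sum(a^2))
  if (sum(abs(u0)) <= c + tol) return(list(u = u0, delta = 0))
  delta <- l1_binding_threshold(abs(a), c)
  if (is.na(delta)) delta <- l1_bisect_threshold(a, c, tol)
  s <- soft_threshold(a, delta)
  if (sum(s^2) == 0) {
    # Tied maxima with multiplicity m > c^2: the L1/L2 ratio plateaus at
    # sqrt(m), so no threshold binds. Spread weight over floor(c^2) of the
    # tied coordinates (deterministically, by index), which is feasible.
    aa <- abs(a); mx <- max(aa)
    idx <- which(aa >= mx * (1 - 1e-12))
    k <- max(1L, min(length(idx), floor(c^2)))
    u <- numeric(length(a))
    u[idx[seq_len(k)]] <- sign(a[idx[seq_len(k)]]) / sqrt(k)
    return(list(u = u, delta = mx))
  }
  list(u = s / sqrt(sum(s^2)), delta = delta)
}

l1_binding_threshold <- function(aa, c) {
  b <- sort(aa, decreasing = TRUE)
  S1 <- cumsum(b); S2 <- cumsum(b^2)
  k <- seq_along(b)
  bnext <- c(b[-1], 0)
  # L1/L2 ratio at the lower end (delta = bnext) of each support-k segment
  h <- (S1 - k * bnext) / sqrt(pmax(S2 - 2 * bnext * S1 + k * bnext^2, 0))
  seg <- which(h >= c)[1]
  if (is.na(seg)) return(NA_real_)
  kk <- seg; s1 <- S1[seg]; s2 <- S2[seg]
  A <- kk * (kk - c^2)
  Bq <- -2 * s1 * (kk - c^2)
  Cq <- s1^2 - c^2 * s2
  if (abs(A) < 1e-300) return(NA_real_)
  disc <- Bq^2 - 4 * A * Cq
  if (disc < 0) return(NA_real_)
  roots <- (-Bq + c(-1, 1) * sqrt(disc)) / (2 * A)
  lo <- bnext[seg]; hi <- b[seg]
  # the true root keeps the thresholded L1 norm positive (S1 - k delta > 0)
  inside <- roots >= lo - 1e-12 & roots <= hi + 1e-12 & (s1 - kk * roots) > 0
  if (!any(inside)) return(NA_real_)
  delta <- max(min(roots[inside][1], hi), lo, 0)
  # accept only if the constraint truly binds at this threshold
  s <- pmax(aa - delta, 0)
  ns <- sqrt(sum(s^2))
  if (ns == 0 || abs(sum(s) / ns - c) > 1e-7 * max(1, c)) return(NA_real_)
  delta
}

l1_bisect_threshold <- function(a, c, tol) {
  lo <- 0; hi <- max(abs(a))
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    s <- soft_threshold(a, mid)
    ns <- sqrt(sum(s^2))
    l1 <- if (ns > 0) sum(abs(s)) / ns else 0
    if (l1 > c) lo <- mid else hi <- mid
    if (hi - lo < 1e-10 * max(abs(a))) break
  }
  hi
}

# Operator view of the (deflated) cross-product Z = Xc'Yc - sum_k s_k u_k v_k'.
# When subjects are far fewer than edges the product is applied through the
# thin factors instead of materializing the p x q matrix.
make_xprod_op <- function(Xc, Yc) {
  factored <- 2L * nrow(Xc) < min(ncol(Xc), ncol(Yc))
  env <- new.env(parent = emptyenv())
  env$factored <- factored
  env$Xc <- Xc; env$Yc <- Yc
  if (!factored) env$Z <- crossprod(Xc, Yc)
  env$U <- NULL; env$V <- NULL; env$s <- numeric(0)
  env
}

xprod_zv <- function(op, v) {
  out <- if (op$factored) {
    as.numeric(crossprod(op$Xc, op$Yc %*% v))
  } else {
    as.numeric(op$Z %*% v)
  }
  if (op$factored && length(op$s)) {
    out <- out - as.numeric(op$U %*% (op$s * as.numeric(crossprod(op$V, v))))
  }
  out
}

xprod_ztu <- function(op, u) {
  out <- if (op$factored) {
    as.numeric(crossprod(op$Yc, op$Xc %*% u))
  } else {
    as.numeric(crossprod(op$Z, u))
  }
  if (op$factored && length(op$s)) {
    out <- out - as.numeric(op$V %*% (op$s * as.numeric(crossprod(op$U, u))))
  }
  out
}

xprod_deflate <- function(op, u, v, sigma) {
  if (op$factored) {
    op$U <- cbind(op$U, u); op$V <- cbind(op$V, v)
    op$s <- c(op$s, sigma)
  } else {
    op$Z <- op$Z - sigma * tcrossprod(u, v)
  }
  invisible(op)
}

# Deterministic power iteration for the leading right singular vector.
leading_right_singular <- function(op, q, iter = 12, tol = 1e-9) {
  cn <- colSums(op$Yc^2)
  v <- numeric(q)
  v[which.max(cn)] <- 1
  for (i in seq_len(iter)) {
    v_new <- xprod_ztu(op, xprod_zv(op, v))
    nv <- sqrt(sum(v_new^2))
    if (nv == 0) return(v)
    v_new <- v_new / nv
    if (sum((v_new - v)^2) < tol^2) { v <- v_new; break }
    v <- v_new
  }
  v
}

qr_rank <- function(M) qr(M)$rank

#' Fit a sparse canonical correlation model
#'
#' Maximizes \eqn{u^\top X^\top Y v} subject to
#' \eqn{\|u\|_2 \le 1, \|v\|_2 \le 1, \|u\|_1 \le c_1, \|v\|_1 \le c_2}
#' by the biconvex alternating algorithm: with `v` fixed the update for
#' `u` has the closed form of an L2-normalized soft-thresholding of
#' \eqn{X^\top Y v} (threshold found by bisection so the L1 bound binds),
#' and symmetrically for `v`. The objective is non-decreasing at every
#' step. Successive components are obtained by deflating the
#' cross-product matrix by the rank-1 term of each converged pair.
#' Columns are centered internally and the means stored for prediction.
#'
#' @param X,Y [edge_dataset()]s or numeric matrices with the same number
#'   of rows (subjects).
#' @param c1,c2 L1 bounds; feasible range is \[1, sqrt(p)\] (resp.
#'   sqrt(q)), since a unit-L2 vector always has L1 norm >= 1.
#' @param K number of canonical components; capped at the minimum of the
#'   ranks of the centered `X` and `Y` (with a warning if reduced).
#' @param tol convergence tolerance on the relative objective change.
#' @param max_iter maximum alternations per component.
#' @return An object of class `scca_fit` with canonical vector matrices
#'   `U` (p x K), `V` (q x K), canonical correlations `d`, penalties,
#'   stored column means, per-component iteration counts, convergence
#'   flags and objective traces. See [predict_y_from_x()],
#'   [predict_x_from_y()], [tidy.scca_fit()], [glance.scca_fit()].
#' @export
scca_fit <- function(X, Y, c1, c2, K = 1, tol = 1e-6, max_iter = 30) {
  Xm <- as_edge_matrix(X); Ym <- as_edge_matrix(Y)
  if (nrow(Xm) != nrow(Ym)) abort("X and Y must have the same number of subjects.")
  p <- ncol(Xm); q <- ncol(Ym)
  if (c1 < 1 || c1 > sqrt(p) + 1e-8) {
    abort(sprintf("`c1` must lie in [1, sqrt(p)] = [1, %.3f].", sqrt(p)))
  }
  if (c2 < 1 || c2 > sqrt(q) + 1e-8) {
    abort(sprintf("`c2` must lie in [1, sqrt(q)] = [1, %.3f].", sqrt(q)))
  }
  x_means <- colMeans(Xm); y_means <- colMeans(Ym)
  Xc <- sweep(Xm, 2, x_means); Yc <- sweep(Ym, 2, y_means)
  K_max <- min(qr_rank(Xc), qr_rank(Yc))
  if (K > K_max) {
    warn(sprintf("K reduced from %d to the minimum rank %d.", K, K_max))
    K <- K_max
  }
  op <- make_xprod_op(Xc, Yc)
  U <- matrix(0, p, K); V <- matrix(0, q, K)
  d <- numeric(K); iters <- integer(K); conv <- logical(K)
  objectives <- vector("list", K)
  for (k in seq_len(K)) {
    v <- leading_right_singular(op, q)
    if (sqrt(sum(xprod_zv(op, v)^2)) < 1e-12) {
      warn(sprintf("Cross-product exhausted at component %d; skipping rest.", k))
      K <- k - 1L
      U <- U[, seq_len(K), drop = FALSE]; V <- V[, seq_len(K), drop = FALSE]
      d <- d[seq_len(K)]; iters <- iters[seq_len(K)]; conv <- conv[seq_len(K)]
      objectives <- objectives[seq_len(K)]
      break
    }
    u <- numeric(p)
    obj <- -Inf; trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      u <- l1_constrained_direction(xprod_zv(op, v), c1)$u
      a <- xprod_ztu(op, u)
      v <- l1_constrained_direction(a, c2)$u
      obj_new <- sum(a * v)
      trace <- c(trace, obj_new)
      if (is.finite(obj) && abs(obj_new - obj) <= tol * max(1, abs(obj))) {
        obj <- obj_new; conv[k] <- TRUE; iters[k] <- it
        break
      }
      obj <- obj_new; iters[k] <- it
    }
    xu <- Xc %*% u; yv <- Yc %*% v
    d[k] <- if (sd(xu) > 0 && sd(yv) > 0) cor(as.numeric(xu), as.numeric(yv)) else 0
    U[, k] <- u; V[, k] <- v
    objectives[[k]] <- trace
    xprod_deflate(op, u, v, obj)
  }
  structure(
    list(U = U, V = V, d = d, c1 = c1, c2 = c2,
         x_means = x_means, y_means = y_means, K = K,
         iterations = iters, converged = conv, objectives = objectives,
         p = p, q = q, n = nrow(Xm)),
    class = "scca_fit")
}

#' @export
print.scca_fit <- function(x, ...) {
  cat(sprintf("<scca_fit> %d component(s), p = %d, q = %d, n = %d\n",
              x$K, x$p, x$q, x$n))
  cat(sprintf("  penalties c1 = %.3f, c2 = %.3f\n", x$c1, x$c2))
  if (x$K > 0) {
    cat(sprintf("  canonical correlations: %s\n",
                paste(sprintf("%.3f", x$d), collapse = ", ")))
  }
  invisible(x)
}

#' Permutation-based selection of the sparsity penalties
#'
#' For each candidate `(c1, c2)` pair a single-component model is fit to
#' the data and to `n_perm` copies with the rows of `X` permuted, which
#' breaks the subject-level correspondence between the two blocks. The
#' grid point maximizing the standardized gap
#' \eqn{(z(d) - \bar z(d_{perm})) / sd(z(d_{perm}))} of
#' Fisher-transformed canonical correlations is selected.
#'
#' @inheritParams scca_fit
#' @param grid tibble/data frame with columns `c1`, `c2`, or `NULL` for
#'   the default grid of 8 L1 bounds at fractions 0.1-0.8 of sqrt(p) and
#'   sqrt(q) (paired, floored at 1).
#' @param n_perm number of row permutations (>= 10).
#' @param seed integer seed for the permutations.
#' @return List with `c1`, `c2` and `diagnostics`, a tibble of the grid
#'   with observed correlation `d`, permutation mean/sd and `score`.
#' @export
select_penalties <- function(X, Y, grid = NULL, n_perm = 25, seed = 1L) {
  Xm <- as_edge_matrix(X); Ym <- as_edge_matrix(Y)
  if (n_perm < 10) abort("`n_perm` must be at least 10.")
  if (is.null(grid)) grid <- default_penalty_grid(ncol(Xm), ncol(Ym))
  grid <- as_tibble(grid)
  if (nrow(grid) == 0) abort("`grid` must be nonempty.")
  n <- nrow(Xm)
  perms <- with_seed(seed, lapply(seq_len(n_perm), function(i) sample.int(n)))
  zt <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  res <- lapply(seq_len(nrow(grid)), function(g) {
    c1 <- grid$c1[g]; c2 <- grid$c2[g]
    d_obs <- scca_fit(Xm, Ym, c1, c2, K = 1, tol = 1e-4, max_iter = 20)$d[1]
    d_perm <- vapply(perms, function(pm) {
      scca_fit(Xm[pm, , drop = FALSE], Ym, c1, c2, K = 1, tol = 1e-4,
               max_iter = 20)$d[1]
    }, numeric(1))
    sd_p <- sd(zt(d_perm))
    score <- if (sd_p > 0) (zt(d_obs) - mean(zt(d_perm))) / sd_p else -Inf
    tibble(c1 = c1, c2 = c2, d = d_obs, perm_mean = mean(d_perm),
           perm_sd = sd(d_perm), score = score)
  })
  diagnostics <- dplyr::bind_rows(res)
  best <- which.max(diagnostics$score)
  list(c1 = diagnostics$c1[best], c2 = diagnostics$c2[best],
       diagnostics = diagnostics)
}

#' Default penalty grid
#'
#' Eight paired L1 bounds at fractions 0.1 to 0.8 of sqrt(p) and sqrt(q),
#' floored at the feasibility bound 1.
#'
#' @param p,q numbers of columns of the two blocks.
#' @param fractions fractions of sqrt(p) (resp. sqrt(q)) to use.
#' @return Tibble with columns `c1`, `c2`.
#' @export
default_penalty_grid <- function(p, q, fractions = seq(0.1, 0.8, by = 0.1)) {
  tibble(c1 = pmax(1, fractions * sqrt(p)),
         c2 = pmax(1, fractions * sqrt(q)))
}

#' Predict one modality's connectome edges from the other
#'
#' Maps a (previously unseen) subject's edge vector through the fitted
#' canonical space: the centered input is projected onto the canonical
#' vectors, scaled by the canonical correlations, and back-projected into
#' the target edge space through the Moore-Penrose pseudoinverse of the
#' target-side canonical vector matrix,
#' \deqn{\hat y = (x - \bar x)^\top U D V^+ + \bar y.}
#' This is reduced-rank prediction through the canonical subspace; when
#' the canonical vectors are orthonormal \eqn{V^+ = V^\top} and the
#' formula is the usual CCA regression.
#'
#' @param model an [scca_fit()].
#' @param x_row numeric vector of length `p` (or a matrix with `p`
#'   columns, one row per subject).
#' @return Predicted edge vector of length `q` (or matrix).
#' @export
predict_y_from_x <- function(model, x_row) {
  stopifnot(inherits(model, "scca_fit"))
  Xr <- if (is.matrix(x_row)) x_row else matrix(x_row, nrow = 1)
  if (ncol(Xr) != model$p) {
    abort(sprintf("Expected %d X-edges, got %d.", model$p, ncol(Xr)))
  }
  if (model$K == 0) {
    out <- matrix(rep(model$y_means, each = nrow(Xr)), nrow(Xr))
  } else {
    scores <- sweep(Xr, 2, model$x_means) %*% model$U
    D <- diag(model$d, nrow = model$K)
    out <- scores %*% D %*% MASS::ginv(model$V) +
      matrix(rep(model$y_means, each = nrow(Xr)), nrow(Xr))
  }
  if (is.matrix(x_row)) out else as.numeric(out)
}

#' @rdname predict_y_from_x
#' @param y_row numeric vector of length `q` (or a matrix with `q`
#'   columns); roles of the two blocks are swapped.
#' @export
predict_x_from_y <- function(model, y_row) {
  stopifnot(inherits(model, "scca_fit"))
  Yr <- if (is.matrix(y_row)) y_row else matrix(y_row, nrow = 1)
  if (ncol(Yr) != model$q) {
    abort(sprintf("Expected %d Y-edges, got %d.", model$q, ncol(Yr)))
  }
  if (model$K == 0) {
    out <- matrix(rep(model$x_means, each = nrow(Yr)), nrow(Yr))
  } else {
    scores <- sweep(Yr, 2, model$y_means) %*% model$V
    D <- diag(model$d, nrow = model$K)
    out <- scores %*% D %*% MASS::ginv(model$U) +
      matrix(rep(model$x_means, each = nrow(Yr)), nrow(Yr))
  }
  if (is.matrix(y_row)) out else as.numeric(out)
}
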