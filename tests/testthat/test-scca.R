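test_that("soft thresholding shrinks toward zero elementwise", {
  expect_equal(soft_threshold(c(2, -0.5, 3), 1), c(1, 0, 2))
  a <- c(-1.5, 0.2, 4)
  expect_equal(soft_threshold(a, 0), a)
  expect_equal(soft_threshold(a, 5), c(0, 0, 0))
  expect_error(soft_threshold(a, -1), "non-negative")
})

test_that("the L1-constrained update satisfies and binds its constraints", {
  set.seed(31)
  for (i in 1:50) {
    p <- sample(5:80, 1)
    a <- rnorm(p)
    if (i %% 4 == 0) a[sample(p, 3)] <- a[1]   # exact ties
    cbound <- runif(1, 1, sqrt(p))
    r <- conncca:::l1_constrained_direction(a, cbound)
    expect_lte(sqrt(sum(r$u^2)), 1 + 1e-8)
    expect_lte(sum(abs(r$u)), cbound + 1e-6)
    if (r$delta > 0 && sum(soft_threshold(a, r$delta)^2) > 0) {
      expect_lt(abs(sum(abs(r$u)) - cbound), 1e-6)  # binding
    }
  }
})

test_that("closed-form threshold agrees with the bisection fallback", {
  set.seed(32)
  for (i in 1:30) {
    p <- sample(5:60, 1)
    a <- rnorm(p)
    cbound <- runif(1, 1.01, sqrt(p) * 0.95)
    d_exact <- conncca:::l1_binding_threshold(abs(a), cbound)
    if (!is.na(d_exact)) {
      d_bis <- conncca:::l1_bisect_threshold(a, cbound, 1e-10)
      expect_equal(d_exact, d_bis, tolerance = 1e-6)
    }
  }
})

test_that("at maximal penalties the first component is the leading singular pair", {
  set.seed(33)
  for (i in 1:5) {
    X <- matrix(rnorm(12 * 20), 12)
    Y <- matrix(rnorm(12 * 15), 12)
    f <- scca_fit(X, Y, sqrt(20), sqrt(15), K = 1, tol = 1e-12,
                  max_iter = 500)
    sv <- svd(crossprod(scale(X, scale = FALSE), scale(Y, scale = FALSE)))
    expect_gt(abs(sum(f$U[, 1] * sv$u[, 1])), 1 - 1e-6)
    expect_gt(abs(sum(f$V[, 1] * sv$v[, 1])), 1 - 1e-6)
  }
})

test_that("the objective is non-decreasing within every component", {
  set.seed(34)
  for (i in 1:8) {
    X <- matrix(rnorm(10 * 30), 10)
    Y <- matrix(rnorm(10 * 25), 10)
    c1 <- runif(1, 1.2, sqrt(30)); c2 <- runif(1, 1.2, sqrt(25))
    f <- scca_fit(X, Y, c1, c2, K = 3)
    for (trace in f$objectives) {
      expect_true(all(diff(trace) >= -1e-9 * max(1, abs(trace[1]))))
    }
    # constraints hold for every returned component
    expect_true(all(colSums(abs(f$U)) <= c1 + 1e-6))
    expect_true(all(colSums(abs(f$V)) <= c2 + 1e-6))
    expect_true(all(sqrt(colSums(f$U^2)) <= 1 + 1e-8))
  }
})

test_that("a planted sparse linkage is recovered at binding penalties", {
  lk <- make_linked_edge_datasets(17, 100, 100, support = 5, score_sd = 3,
                                  noise_sd = 0.2, seed = 35)
  f <- scca_fit(lk$X, lk$Y, 2.2, 2.2, K = 1)
  expect_true(all(f$U[lk$linkage$support_x, 1] != 0))
  expect_true(all(f$V[lk$linkage$support_y, 1] != 0))
  # off-support coefficients are sparse at a binding c1
  expect_lt(sum(f$U[, 1] != 0), 30)
  expect_gt(f$d[1], 0.9)
})

test_that("K is capped at the minimum rank with a warning", {
  set.seed(36)
  X <- matrix(rnorm(5 * 10), 5)
  Y <- matrix(rnorm(5 * 10), 5)
  expect_warning(f <- scca_fit(X, Y, 2, 2, K = 10), "minimum rank")
  expect_lte(f$K, 4)
  expect_error(scca_fit(X, Y, 0.5, 2), "c1")
  expect_error(scca_fit(X, matrix(rnorm(12), 6, 2), 2, 1), "same number")
})

test_that("swapping the blocks swaps the canonical vectors on a unique-optimum fixture", {
  lk <- make_linked_edge_datasets(15, 40, 30, support = 4, score_sd = 3,
                                  noise_sd = 0.05, seed = 37)
  f1 <- scca_fit(lk$X, lk$Y, 2.5, 2.5, K = 1, tol = 1e-10, max_iter = 200)
  f2 <- scca_fit(lk$Y, lk$X, 2.5, 2.5, K = 1, tol = 1e-10, max_iter = 200)
  expect_gt(abs(sum(f1$U[, 1] * f2$V[, 1])), 1 - 1e-4)
  expect_gt(abs(sum(f1$V[, 1] * f2$U[, 1])), 1 - 1e-4)
})

test_that("penalty selection returns the only grid point and flags strong linkage", {
  lk <- make_linked_edge_datasets(16, 60, 60, support = 4, score_sd = 3,
                                  noise_sd = 0.2, seed = 38)
  one <- select_penalties(lk$X, lk$Y, grid = data.frame(c1 = 2, c2 = 2),
                          n_perm = 10, seed = 1)
  expect_equal(one$c1, 2)
  expect_equal(one$c2, 2)
  sel <- select_penalties(lk$X, lk$Y, n_perm = 12, seed = 2)
  expect_gt(max(sel$diagnostics$score), 2)
  expect_error(select_penalties(lk$X, lk$Y, n_perm = 5), "at least 10")
})

test_that("noiseless rank-1 linkage is predicted exactly in both directions", {
  lk <- make_linked_edge_datasets(12, 25, 18, support = 4, score_sd = 2,
                                  noise_sd = 0, seed = 39)
  tr <- 1:11; te <- 12
  f <- scca_fit(lk$X$matrix[tr, ], lk$Y$matrix[tr, ], sqrt(25), sqrt(18),
                K = 1, tol = 1e-12, max_iter = 500)
  yhat <- predict_y_from_x(f, lk$X$matrix[te, ])
  xhat <- predict_x_from_y(f, lk$Y$matrix[te, ])
  expect_lt(max(abs(yhat - lk$Y$matrix[te, ])) / max(abs(lk$Y$matrix[te, ])),
            1e-6)
  expect_lt(max(abs(xhat - lk$X$matrix[te, ])) / max(abs(lk$X$matrix[te, ])),
            1e-6)
})

test_that("predicting from the column means returns the target means", {
  set.seed(40)
  X <- matrix(rnorm(8 * 10), 8)
  Y <- matrix(rnorm(8 * 12), 8)
  f <- scca_fit(X, Y, 2, 2, K = 2)
  expect_equal(predict_y_from_x(f, f$x_means), unname(f$y_means),
               ignore_attr = TRUE)
  expect_equal(predict_x_from_y(f, f$y_means), unname(f$x_means),
               ignore_attr = TRUE)
  expect_error(predict_y_from_x(f, rnorm(5)), "Expected 10")
  expect_error(predict_x_from_y(f, rnorm(5)), "Expected 12")
})

test_that("predictions of connectome-derived fixtures devectorize to SPD matrices", {
  set.seed(41)
  labs <- sprintf("r%d", 1:8)
  mats <- lapply(1:10, function(i) {
    X <- matrix(rnorm(200 * 8), 200) %*% chol(random_spd(8))
    normalized_precision(shrinkage_covariance(X))
  })
  ed <- edge_dataset_from_connectomes(mats)
  f <- scca_fit(ed, ed, 2, 2, K = 1)
  yhat <- predict_y_from_x(f, ed$matrix[3, ])
  M <- devectorize_edges(yhat, mats[[1]]$labels)
  expect_true(check_spd(M)$spd)
})
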