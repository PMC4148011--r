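test_that("forced full shrinkage returns the identity", {
  set.seed(1)
  X <- matrix(rnorm(40 * 5), 40)
  cv <- shrinkage_covariance(X, lambda = 1)
  expect_equal(cv$matrix, diag(5), ignore_attr = TRUE)
  expect_equal(cv$shrinkage_lambda, 1)
})

test_that("analytic shrinkage improves on the sample covariance (Monte Carlo)", {
  set.seed(21)
  R <- 20; T_ <- 40
  Sigma <- random_spd(R, jitter = 0.5)
  ch <- chol(Sigma)
  err <- replicate(30, {
    X <- matrix(rnorm(T_ * R), T_) %*% ch
    cv <- shrinkage_covariance(X)
    expect_true(cv$shrinkage_lambda >= 0 && cv$shrinkage_lambda <= 1)
    expect_true(check_spd(cv$matrix)$spd)
    c(shrunk = norm(cv$matrix - Sigma, "F"), raw = norm(cov(X) - Sigma, "F"))
  })
  expect_lt(mean(err["shrunk", ]), mean(err["raw", ]))
})

test_that("shrinkage intensity vanishes as samples grow", {
  set.seed(22)
  Sigma <- random_spd(5)
  ch <- chol(Sigma)
  lam_small <- shrinkage_covariance(matrix(rnorm(30 * 5), 30) %*% ch)$shrinkage_lambda
  big <- shrinkage_covariance(matrix(rnorm(10000 * 5), 10000) %*% ch)
  expect_lt(big$shrinkage_lambda, 0.02)
  expect_lt(big$shrinkage_lambda, lam_small)
  expect_lt(norm(big$matrix - Sigma, "F") / norm(Sigma, "F"), 0.1)
})

test_that("degenerate constant input still yields an SPD estimate", {
  X <- matrix(1, 20, 3)
  cv <- shrinkage_covariance(X)
  expect_true(check_spd(cv$matrix)$spd)
  expect_error(shrinkage_covariance(matrix(1, 1, 3)), "at least 2")
})

test_that("shrunk eigenvalues respect the convex-combination bounds", {
  set.seed(23)
  X <- matrix(rnorm(50 * 8), 50) %*% chol(random_spd(8))
  cv <- shrinkage_covariance(X)
  lam <- cv$shrinkage_lambda
  ev_s <- eigen(cov(X), symmetric = TRUE, only.values = TRUE)$values
  ev <- eigen(cv$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), lam + (1 - lam) * min(ev_s) - 1e-10)
  expect_lte(max(ev), lam + (1 - lam) * max(ev_s) + 1e-10)
})

test_that("normalized precision inverts, rescales, and finds conditional independence", {
  expect_equal(normalized_precision(diag(4))$matrix, diag(4),
               ignore_attr = TRUE)
  rho <- 0.7
  np <- normalized_precision(matrix(c(1, rho, rho, 1), 2))
  expect_equal(np$matrix[1, 2], -rho)
  # chain A-B-C: construct Sigma from a sparse precision with (A,C) zero
  P <- matrix(c(2, -0.8, 0, -0.8, 2, -0.8, 0, -0.8, 2), 3)
  np2 <- normalized_precision(solve(P))
  expect_lt(abs(np2$matrix[1, 3]), 1e-10)
  expect_gt(abs(np2$matrix[1, 2]), 0.1)
  expect_error(normalized_precision(diag(c(1, -1))), "min eigenvalue")
})

test_that("normalized precision is invariant to per-region rescaling", {
  set.seed(24)
  X <- matrix(rnorm(60 * 6), 60) %*% chol(random_spd(6))
  scale_f <- runif(6, 0.5, 5)
  np1 <- normalized_precision(shrinkage_covariance(X, lambda = 0))
  np2 <- normalized_precision(shrinkage_covariance(sweep(X, 2, scale_f, `*`),
                                                   lambda = 0))
  expect_equal(np1$matrix, np2$matrix, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("partial correlation matches the residualized-regression oracle", {
  set.seed(25)
  Sigma <- random_spd(4, jitter = 0.8)
  X <- matrix(rnorm(5000 * 4), 5000) %*% chol(Sigma)
  np <- normalized_precision(shrinkage_covariance(X, lambda = 0))
  pc <- partial_correlation(np)
  # oracle: correlation of residuals after regressing out the other regions
  for (pair in list(c(1, 2), c(2, 4), c(1, 3))) {
    i <- pair[1]; j <- pair[2]
    others <- setdiff(1:4, pair)
    ri <- lm.fit(cbind(1, X[, others]), X[, i])$residuals
    rj <- lm.fit(cbind(1, X[, others]), X[, j])$residuals
    expect_equal(pc[i, j], cor(ri, rj), tolerance = 1e-6)
  }
  expect_equal(partial_correlation(normalized_precision(diag(3)))[1, 2], 0)
})

test_that("edge vectorization counts edges and round-trips", {
  expect_length(vectorize_edges(diag(3)), 3)
  labs68 <- region_label_fixture(FALSE)
  labs82 <- region_label_fixture(TRUE)
  expect_length(labs68, 68)
  expect_length(labs82, 82)
  expect_equal(choose(68, 2), 2278)
  expect_equal(choose(82, 2), 3321)
  set.seed(26)
  M <- devectorize_edges(rnorm(choose(10, 2)), sprintf("r%d", 1:10))
  expect_equal(devectorize_edges(vectorize_edges(M), rownames(M)), M)
  expect_error(devectorize_edges(1:5, c("a", "b", "c")), "Expected 3 edges")
})

test_that("edge order is row-major over the upper triangle", {
  M <- diag(3)
  M[1, 2] <- M[2, 1] <- 12
  M[1, 3] <- M[3, 1] <- 13
  M[2, 3] <- M[3, 2] <- 23
  expect_equal(unname(vectorize_edges(M)), c(12, 13, 23))
})

test_that("top-fraction thresholding ranks by absolute value with the tie rule", {
  M <- devectorize_edges(c(0.9, -0.5, 0.1), c("a", "b", "c"))
  top <- threshold_top_fraction(M, 2 / 3)
  expect_equal(nrow(top), 2)
  expect_equal(top$weight, c(0.9, -0.5))
  expect_equal(top$sign, c("positive", "negative"))
  expect_equal(nrow(threshold_top_fraction(M, 1)), 3)
  # exact ties broken by edge order, count exact
  M2 <- devectorize_edges(c(0.5, 0.5, 0.5), c("a", "b", "c"))
  top2 <- threshold_top_fraction(M2, 2 / 3)
  expect_equal(nrow(top2), 2)
  expect_equal(top2$region_j, c("b", "c"))  # edges 1 and 2 in index order
  expect_error(threshold_top_fraction(M, 0), "fraction")
})

test_that("group averaging is the element-wise mean (linearity)", {
  set.seed(27)
  cs <- lapply(1:4, function(i) {
    connectome(devectorize_edges(rnorm(choose(5, 2), sd = 0.2),
                                 sprintf("r%d", 1:5)),
               kind = "normalized_precision")
  })
  avg <- group_average_connectome(cs)
  expect_equal(avg$matrix,
               Reduce(`+`, lapply(cs, function(x) x$matrix)) / 4,
               ignore_attr = TRUE)
  expect_equal(diag(avg$matrix), rep(1, 5), ignore_attr = TRUE)
})
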