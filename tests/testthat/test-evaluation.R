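test_that("rank-sum test matches brute-force enumeration on the textbook case", {
  rs <- ranksum_compare(c(1, 2, 3), c(10, 11, 12))
  expect_equal(rs$p.value, 0.1)
  expect_equal(unname(rs$statistic), 6)
  same <- ranksum_compare(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p.value, 0.9)
})

test_that("rank-sum exact path agrees with the reference implementation", {
  set.seed(61)
  for (i in 1:40) {
    m <- sample(3:6, 1); n <- sample(3:6, 1)
    a <- rnorm(m); b <- rnorm(n, mean = runif(1, -1, 1))
    mine <- ranksum_compare(a, b)
    ref <- wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("rank-sum normal approximation matches the reference on larger samples", {
  set.seed(62)
  for (i in 1:100) {
    m <- sample(8:25, 1); n <- sample(8:25, 1)
    a <- rnorm(m); b <- rnorm(n, mean = runif(1, -0.5, 0.5))
    if (i %% 3 == 0) { a <- round(a, 1); b <- round(b, 1) }  # ties
    mine <- ranksum_compare(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-6)
  }
})

test_that("paired signed-rank test enumerates small samples exactly", {
  pw <- paired_wilcoxon(c(2, 4, 6, 8, 10, 12), c(1, 2, 3, 4, 5, 6))
  expect_equal(pw$p.value, 2 / 64)
  expect_warning(deg <- paired_wilcoxon(1:5, 1:5), "degenerate")
  expect_equal(deg$p.value, 1)
  set.seed(63)
  for (i in 1:30) {
    n <- sample(4:9, 1)
    a <- rnorm(n); b <- a + rnorm(n, mean = runif(1, -1, 1))
    mine <- paired_wilcoxon(a, b)
    ref <- wilcox.test(a, b, paired = TRUE, exact = TRUE, correct = FALSE)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("paired signed-rank approximation matches the reference on larger samples", {
  set.seed(64)
  for (i in 1:100) {
    n <- sample(14:30, 1)
    a <- rnorm(n); b <- a + rnorm(n, mean = runif(1, -0.5, 0.5))
    mine <- paired_wilcoxon(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                        correct = FALSE))
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-6)
  }
  expect_error(paired_wilcoxon(1:4, 1:5), "matched")
})

test_that("intermodal distances behave like the underlying metric", {
  set.seed(65)
  A <- lapply(1:4, function(i) random_spd(5))
  r0 <- intermodal_distance(A, A)
  expect_equal(nrow(r0), 4)
  expect_true(all(r0$distance < 1e-7))
  B <- A
  B[[2]] <- diag(c(exp(2), 1, 1, 1, 1)) %*% A[[2]]
  B[[2]] <- (B[[2]] + t(B[[2]])) / 2
  # scaling one subject by diag(e^2, 1, ...) moves it by exactly 2 when the
  # base matrix is the identity
  C1 <- list(diag(5)); C2 <- list(diag(c(exp(2), 1, 1, 1, 1)))
  expect_equal(intermodal_distance(C1, C2)$distance, 2)
  # joint affine transform leaves distances unchanged
  M <- matrix(rnorm(25), 5)
  At <- lapply(A, function(P) M %*% P %*% t(M))
  Bt <- lapply(B, function(P) M %*% P %*% t(M))
  expect_equal(intermodal_distance(At, Bt)$distance,
               intermodal_distance(A, B)$distance, tolerance = 1e-7)
  expect_error(intermodal_distance(A, A[1:2]), "matched")
})

test_that("intersubject variability enumerates unordered pairs", {
  set.seed(66)
  mats <- lapply(1:5, function(i) random_spd(4))
  r <- intersubject_variability(mats)
  expect_equal(nrow(r), choose(5, 2))
  expect_true(all(r$distance > 0))
  same <- intersubject_variability(list(diag(3), diag(3), diag(3)))
  expect_true(all(same$distance < 1e-7))
  expect_error(intersubject_variability(list(diag(2))), "at least 2")
})

test_that("intersubject variability grows with the generator's subject deviation", {
  med <- sapply(c(0.2, 2), function(dev) {
    sp <- synthetic_spec(n_subjects = 6, n_regions = 6, n_samples = 600,
                         sampling_rate = 50, bands = list(alpha = c(8, 13)),
                         coupling = 0.8, subject_dev = dev, seed = 67,
                         deviation_rank = 3, deviation_dof = 3)
    sim <- make_coupled_timeseries(sp, carriers = FALSE)
    mats <- lapply(sim$subjects, function(s) s$covariance)
    median(intersubject_variability(mats)$distance)
  })
  expect_gt(med[2], med[1])
})

test_that("leave-one-out prediction returns one distance per subject and direction", {
  set.seed(68)
  labs <- sprintf("r%d", 1:6)
  mats <- lapply(1:6, function(i) {
    X <- matrix(rnorm(150 * 6), 150) %*% chol(random_spd(6))
    normalized_precision(shrinkage_covariance(X))
  })
  ed <- edge_dataset_from_connectomes(mats)
  rep <- loo_predict(ed, ed, grid = data.frame(c1 = 2, c2 = 2),
                     n_perm = 10, seed = 1)
  expect_equal(nrow(rep), 12)
  expect_equal(sort(unique(rep$direction)), c("x_from_y", "y_from_x"))
  expect_equal(unname(table(rep$direction)), c(6L, 6L), ignore_attr = TRUE)
  expect_true(all(rep$distance >= 0, na.rm = TRUE))
  expect_error(loo_predict(edge_dataset(matrix(rnorm(30), 3)), ed),
               "at least 4")
  s <- summary(rep)
  expect_true(all(c("group", "median", "iqr") %in% names(s)))
})
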