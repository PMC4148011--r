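test_that("spec validation enforces bounds", {
  expect_error(synthetic_spec(n_samples = 0), "positive")
  expect_error(synthetic_spec(coupling = 1.2), "0, 1")
  expect_error(synthetic_spec(bands = list(alpha = c(8, 13)),
                              sampling_rate = 20), "Nyquist")
  expect_error(synthetic_spec(bands = list(c(1, 4))), "named")
  expect_warning(synthetic_spec(n_regions = 30, n_samples = 200,
                                sampling_rate = 250), "noisy")
})

small_spec <- function(coupling, subject_dev = 0.5, n_subjects = 3,
                       n_samples = 3000, seed = 1) {
  synthetic_spec(n_subjects = n_subjects, n_regions = 6,
                 n_samples = n_samples, sampling_rate = 50,
                 bands = list(alpha = c(8, 13), beta = c(14, 20)),
                 coupling = coupling, subject_dev = subject_dev, seed = seed,
                 deviation_rank = 3, deviation_dof = 3)
}

test_that("subject covariances are SPD and generation is seed-reproducible", {
  sim <- make_coupled_timeseries(small_spec(0.5), carriers = FALSE)
  for (s in sim$subjects) {
    expect_true(check_spd(s$covariance)$spd)
    expect_true(all(s$envelopes$alpha$values > 0))
  }
  sim2 <- make_coupled_timeseries(small_spec(0.5), carriers = FALSE)
  expect_equal(sim$subjects[[2]]$slow$values, sim2$subjects[[2]]$slow$values)
  sim3 <- make_coupled_timeseries(small_spec(0.5, seed = 2), carriers = FALSE)
  expect_false(identical(sim$subjects[[1]]$slow$values,
                         sim3$subjects[[1]]$slow$values))
})

test_that("with full coupling and no deviation the log-envelope covariance converges", {
  errs <- sapply(c(2000, 16000), function(n) {
    sp <- synthetic_spec(n_subjects = 1, n_regions = 5, n_samples = n,
                         sampling_rate = 50, bands = list(alpha = c(8, 13)),
                         coupling = 1, subject_dev = 0, seed = 9)
    sim <- make_coupled_timeseries(sp, carriers = FALSE)
    s <- sim$subjects[[1]]
    le <- log(s$envelopes$alpha$values) / sp$env_log_sd
    norm(cov(le) - s$covariance, "F") / norm(s$covariance, "F")
  })
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 0.35)
})

test_that("decoupled envelope edges are uncorrelated with slow-modality edges", {
  sp <- synthetic_spec(n_subjects = 20, n_regions = 6, n_samples = 4320,
                       sampling_rate = 50, bands = list(alpha = c(8, 13)),
                       coupling = 0, subject_dev = 1, seed = 31,
                       deviation_rank = 3, deviation_dof = 3)
  sim <- make_coupled_timeseries(sp, carriers = FALSE)
  slow_edges <- t(sapply(sim$subjects, function(s) {
    vectorize_edges(cov(s$slow$values))
  }))
  env_edges <- t(sapply(sim$subjects, function(s) {
    vectorize_edges(cov(log(s$envelopes$alpha$values)))
  }))
  cors <- sapply(seq_len(ncol(slow_edges)), function(j) {
    cor(slow_edges[, j], env_edges[, j])
  })
  expect_lt(abs(mean(cors)), 0.25)
})

test_that("inter-band envelope correlations are low", {
  sim <- make_coupled_timeseries(small_spec(0.8, n_subjects = 2,
                                            n_samples = 6000), carriers = FALSE)
  rs <- unlist(lapply(sim$subjects, function(s) {
    sapply(seq_len(6), function(j) {
      cor(s$envelopes$alpha$values[, j], s$envelopes$beta$values[, j])
    })
  }))
  expect_lt(median(abs(rs)), 0.2)
})

test_that("banded series carry the planted envelope", {
  sim <- make_coupled_timeseries(small_spec(0.8, n_subjects = 1,
                                            n_samples = 6000))
  s <- sim$subjects[[1]]
  env_rec <- hilbert_envelope(s$bands$alpha)
  r <- cor(as.numeric(env_rec$values[, 1]),
           as.numeric(s$envelopes$alpha$values[, 1]))
  expect_gt(r, 0.85)
})

test_that("linked edge datasets plant an exact rank-1 cross-structure", {
  lk <- make_linked_edge_datasets(10, 12, 9, support = 3, score_sd = 2,
                                  noise_sd = 0, seed = 6)
  expect_equal(sum(lk$linkage$u_star != 0), 3)
  expect_equal(sum(lk$linkage$v_star != 0), 3)
  expect_equal(sqrt(sum(lk$linkage$u_star^2)), 1)
  Xc <- scale(lk$X$matrix, scale = FALSE)
  Yc <- scale(lk$Y$matrix, scale = FALSE)
  Z <- crossprod(Xc, Yc)
  sv <- svd(Z)
  expect_lt(sv$d[2] / sv$d[1], 1e-10)   # exactly rank 1
  expect_gt(abs(sum(sv$u[, 1] * lk$linkage$u_star)), 1 - 1e-10)
  expect_gt(abs(sum(sv$v[, 1] * lk$linkage$v_star)), 1 - 1e-10)
})

test_that("score_sd = 0 yields a null linkage under permutation", {
  lk <- make_linked_edge_datasets(15, 30, 30, support = 4, score_sd = 0,
                                  noise_sd = 1, seed = 8)
  d_obs <- scca_fit(lk$X, lk$Y, 2, 2, K = 1)$d[1]
  set.seed(81)
  d_perm <- replicate(60, {
    pm <- sample.int(15)
    scca_fit(lk$X$matrix[pm, ], lk$Y, 2, 2, K = 1)$d[1]
  })
  expect_gt(mean(d_perm >= d_obs), 0.05)  # observed not in the extreme tail
})

test_that("linked dataset preconditions are enforced", {
  expect_error(make_linked_edge_datasets(10, 5, 5, support = 0), "at least 1")
  expect_error(make_linked_edge_datasets(10, 5, 5, support = 6), "min")
  expect_error(make_linked_edge_datasets(2, 5, 5, support = 2), "3 subjects")
})

test_that("Wishart pairs are SPD, concentrate with dof, and validate dof", {
  pairs <- make_wishart_pairs(10, 20, 3, seed = 5)
  expect_length(pairs, 3)
  for (pr in pairs) {
    expect_true(check_spd(pr[[1]])$spd)
    expect_true(check_spd(pr[[2]])$spd)
  }
  med_d <- sapply(c(20, 200), function(dof) {
    ps <- make_wishart_pairs(10, dof, 30, seed = 5)
    median(sapply(ps, function(pr) dai(pr[[1]], pr[[2]])))
  })
  expect_lt(med_d[2], med_d[1] / 2)
  expect_error(make_wishart_pairs(10, 9, 2), "at least the matrix order")
})

test_that("region label fixture matches the atlas layout", {
  l68 <- region_label_fixture(FALSE)
  l82 <- region_label_fixture(TRUE)
  expect_length(l68, 68)
  expect_length(l82, 82)
  expect_false(anyDuplicated(l68) > 0)
  expect_false(anyDuplicated(l82) > 0)
  # subcortical labels come first
  expect_true(all(grepl("thalamus|caudate|putamen|pallidum|hippocampus|amygdala|accumbens",
                        l82[1:14])))
  expect_identical(l82[15:82], l68)
})
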