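#' Leave-one-out cross-validated bidirectional connectome prediction
#'
#' For every held-out subject the sparsity penalties are re-selected on
#' the training folds by the permutation criterion, a sparse CCA is fit
#' with as many components as the minimum rank of the training blocks,
#' the held-out connectome is predicted in each direction, devectorized
#' to a unit-diagonal symmetric matrix, checked for positive definiteness
#' (repaired and counted when not, since the canonical-vector prediction
#' carries no SPD guarantee), and compared to the measured connectome by
#' the affine-invariant distance.
#'
#' @param X,Y [edge_dataset()]s (subjects x edges) of the two modalities,
#'   with `labels` set so rows can be devectorized.
#' @param grid,n_perm penalty-selection controls (see
#'   [select_penalties()]).
#' @param K components per fold; default the minimum rank of the centered
#'   training blocks.
#' @param calibration optional [calibrate_order_normalization()] result;
#'   when supplied normalized distances are reported alongside raw ones.
#' @param repair repair non-SPD predictions (`TRUE`, default) or record
#'   them as missing (`FALSE`).
#' @param seed integer seed driving per-fold permutation streams.
#' @return A `distance_report` tibble with one row per subject and
#'   direction (`"y_from_x"`, `"x_from_y"`): columns `subject`,
#'   `direction`, `distance`, `normalized_distance` (if calibrated),
#'   `repaired`, `c1`, `c2`.
#' @export
loo_predict <- function(X, Y, grid = NULL, n_perm = 25, K = NULL,
                        calibration = NULL, repair = TRUE, seed = 1L) {
  Xm <- as_edge_matrix(X); Ym <- as_edge_matrix(Y)
  S <- nrow(Xm)
  if (S < 4) abort("Need at least 4 subjects for leave-one-out evaluation.")
  labels_x <- edge_labels_for(X)
  labels_y <- edge_labels_for(Y)
  seeds <- derive_seeds(seed, S)
  rows <- list()
  for (s in seq_len(S)) {
    tr <- setdiff(seq_len(S), s)
    Xtr <- Xm[tr, , drop = FALSE]; Ytr <- Ym[tr, , drop = FALSE]
    sel <- select_penalties(Xtr, Ytr, grid = grid, n_perm = n_perm,
                            seed = seeds[s])
    Kf <- K %||% min(qr_rank(sweep(Xtr, 2, colMeans(Xtr))),
                     qr_rank(sweep(Ytr, 2, colMeans(Ytr))))
    fit <- suppressWarnings(scca_fit(Xtr, Ytr, sel$c1, sel$c2, K = Kf))
    yhat <- predict_y_from_x(fit, Xm[s, ])
    xhat <- predict_x_from_y(fit, Ym[s, ])
    rows[[length(rows) + 1L]] <-
      score_prediction(yhat, Ym[s, ], labels_y, "y_from_x", s, sel,
                       calibration, repair)
    rows[[length(rows) + 1L]] <-
      score_prediction(xhat, Xm[s, ], labels_x, "x_from_y", s, sel,
                       calibration, repair)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("distance_report", class(out))
  out
}

edge_labels_for <- function(X) {
  if (inherits(X, "edge_dataset") && !is.null(X$labels)) return(X$labels)
  p <- ncol(as_edge_matrix(X))
  R <- (1 + sqrt(1 + 8 * p)) / 2
  if (abs(R - round(R)) > 1e-8) {
    abort("Edge count is not R(R-1)/2 for any integer R; supply labels.")
  }
  sprintf("R%02d", seq_len(round(R)))
}

score_prediction <- function(pred_edges, true_edges, labels, direction,
                             subject, sel, calibration, repair) {
  Pred <- devectorize_edges(pred_edges, labels)
  True <- devectorize_edges(as.numeric(true_edges), labels)
  chk <- check_spd(Pred)
  repaired <- FALSE
  if (!chk$spd) {
    if (!repair) {
      return(tibble(subject = subject, direction = direction,
                    distance = NA_real_, normalized_distance = NA_real_,
                    repaired = NA, c1 = sel$c1, c2 = sel$c2,
                    note = sprintf("non-SPD prediction (min eig %.3g)",
                                   chk$min_eigenvalue)))
    }
    rp <- repair_spd(Pred)
    Pred <- rp$matrix
    repaired <- rp$repaired
  }
  dist <- dai(Pred, True)
  tibble(subject = subject, direction = direction, distance = dist,
         normalized_distance = if (!is.null(calibration)) {
           suppressWarnings(normalized_dai(Pred, True, calibration))
         } else NA_real_,
         repaired = repaired, c1 = sel$c1, c2 = sel$c2, note = NA_character_)
}

#' Within-subject distance between two modalities' connectomes
#'
#' @param A,B lists of per-subject [connectome()]s (or SPD matrices),
#'   matched by position.
#' @return A `distance_report` tibble with `subject`, `distance` (and
#'   `normalized_distance` when a calibration is given).
#' @param calibration optional order calibration for normalized output.
#' @export
intermodal_distance <- function(A, B, calibration = NULL) {
  if (length(A) != length(B)) abort("A and B must have matched subjects.")
  rows <- lapply(seq_along(A), function(s) {
    P <- as_conn_matrix(A[[s]]); G <- as_conn_matrix(B[[s]])
    tibble(subject = s, condition = "intermodal", distance = dai(P, G),
           normalized_distance = if (!is.null(calibration)) {
             suppressWarnings(normalized_dai(P, G, calibration))
           } else NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("distance_report", class(out))
  out
}

#' Inter-subject variability of connectomes within one modality
#'
#' Affine-invariant distance over all unordered subject pairs.
#'
#' @param mats list of per-subject [connectome()]s (or SPD matrices).
#' @param calibration optional order calibration.
#' @return A `distance_report` tibble with `subject_i`, `subject_j`,
#'   `distance`, one row per unordered pair.
#' @export
intersubject_variability <- function(mats, calibration = NULL) {
  S <- length(mats)
  if (S < 2) abort("Need at least 2 subjects.")
  pairs <- combn(S, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    P <- as_conn_matrix(mats[[i]]); G <- as_conn_matrix(mats[[j]])
    tibble(subject_i = i, subject_j = j, condition = "intersubject",
           distance = dai(P, G),
           normalized_distance = if (!is.null(calibration)) {
             suppressWarnings(normalized_dai(P, G, calibration))
           } else NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("distance_report", class(out))
  out
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test for a location difference between independent
#' samples. For combined sample sizes up to `exact_max` the null
#' distribution of the rank-sum is enumerated exactly over all
#' assignments of the (mid-)ranks, which handles ties without
#' approximation; for larger samples a tie-corrected normal approximation
#' is used.
#'
#' @param a,b numeric vectors (or `distance_report`s, from which the
#'   `distance` column is taken). Samples are assumed independent.
#' @param exact_max largest combined size for exact enumeration
#'   (default 12).
#' @return A list of class `htest` with `statistic` (rank-sum of `a`),
#'   `p.value`, and `method`.
#' @export
ranksum_compare <- function(a, b, exact_max = 12) {
  a <- report_values(a); b <- report_values(b)
  m <- length(a); n <- length(b)
  if (m < 1 || n < 1) abort("Both samples must be non-empty.")
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(m)])
  if (m + n <= exact_max) {
    sets <- combn(m + n, m)
    ws <- colSums(matrix(r[sets], nrow = m))
    e <- mean(ws)
    p <- mean(abs(ws - e) >= abs(w_obs - e) - 1e-9)
    method <- "Wilcoxon rank-sum test (exact enumeration)"
  } else {
    e <- m * (n + m + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / ((m + n) * (m + n - 1))
    v <- m * n / 12 * ((m + n + 1) - tie_term)
    z <- (w_obs - e) / sqrt(v)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "Wilcoxon rank-sum test (tie-corrected normal approximation)"
  }
  structure(list(statistic = c(W = w_obs), p.value = p, method = method,
                 data.name = "a and b"),
            class = "htest")
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on matched samples; zero differences are
#' dropped. Exact enumeration over the 2^n sign patterns is used for up
#' to `exact_max` nonzero differences, a tie-corrected normal
#' approximation beyond.
#'
#' @param a,b matched numeric vectors of equal length (or
#'   `distance_report`s).
#' @param exact_max largest number of nonzero differences for exact
#'   enumeration (default 12).
#' @return A list of class `htest` with `statistic` (positive-rank sum
#'   `V`), `p.value`, `method`.
#' @export
paired_wilcoxon <- function(a, b, exact_max = 12) {
  a <- report_values(a); b <- report_values(b)
  if (length(a) != length(b)) abort("Samples must be matched (equal length).")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warn("All paired differences are zero; test is degenerate, p = 1.")
    return(structure(list(statistic = c(V = 0), p.value = 1,
                          method = "Wilcoxon signed-rank test (degenerate)",
                          data.name = "a and b"), class = "htest"))
  }
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- as.numeric(signs %*% r)
    e <- mean(vs)
    p <- mean(abs(vs - e) >= abs(v_obs - e) - 1e-9)
    method <- "Wilcoxon signed-rank test (exact enumeration)"
  } else {
    e <- n * (n + 1) / 4
    ties <- table(r)
    v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v_obs - e) / sqrt(v)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "Wilcoxon signed-rank test (tie-corrected normal approximation)"
  }
  structure(list(statistic = c(V = v_obs), p.value = p, method = method,
                 data.name = "a and b"),
            class = "htest")
}

report_values <- function(x) {
  if (inherits(x, "distance_report") || (is.data.frame(x) && "distance" %in% names(x))) {
    v <- x$distance
  } else {
    v <- as.numeric(x)
  }
  v[!is.na(v)]
}

#' Summarize a distance report
#'
#' Medians and interquartile ranges per direction/condition group.
#'
#' @param object a `distance_report` tibble.
#' @param ... unused.
#' @return A tibble with `group`, `n`, `median`, `iqr`, `n_repaired`.
#' @export
summary.distance_report <- function(object, ...) {
  grp <- if ("direction" %in% names(object)) object$direction
         else if ("condition" %in% names(object)) object$condition
         else rep("all", nrow(object))
  parts <- split(seq_len(nrow(object)), grp)
  dplyr::bind_rows(lapply(names(parts), function(nm) {
    g <- object[parts[[nm]], , drop = FALSE]
    tibble(group = nm,
           n = sum(!is.na(g$distance)),
           median = median(g$distance, na.rm = TRUE),
           iqr = stats::IQR(g$distance, na.rm = TRUE),
           n_repaired = if ("repaired" %in% names(g)) sum(g$repaired, na.rm = TRUE) else 0L)
  }))
}

#' One replicate of the coupled-cohort prediction experiment
#'
#' Generates a synthetic cohort with a planted cross-modal coupling,
#' estimates each subject's normalized-precision connectome in both
#' modalities (the fast modality at the envelope level), and evaluates
#' leave-one-out sparse-CCA prediction of the slow-modality connectome
#' from the fast one. Two reference levels accompany the cross-validated
#' distances: the distance from each held-out subject's measured
#' connectome to the element-wise group mean of the remaining subjects'
#' connectomes (the best subject-independent predictor), and the mean
#' pairwise distance to the other subjects' connectomes.
#'
#' @param coupling shared fraction of envelope covariance, in \[0, 1\].
#' @param n_subjects,n_regions cohort dimensions.
#' @param n_samples,sampling_rate fast-modality series length and rate.
#' @param band envelope band in Hz.
#' @param subject_dev,deviation_rank,deviation_dof subject-deviation
#'   parameters (see [synthetic_spec()]).
#' @param epoch_seconds slow-modality sampling interval in seconds
#'   (default 0.72, a fast multiband-style repetition time, so the slow
#'   modality's covariance is estimated from enough samples for the
#'   inter-subject structure to rise above estimation noise).
#' @param grid_fractions penalty-grid L1 bounds as fractions of sqrt(p).
#' @param n_perm permutations per penalty selection.
#' @param seed integer seed.
#' @return A list with `loo` (the `distance_report` for the
#'   slow-from-fast direction), `baseline_mean`, `baseline_pairwise`
#'   (per-subject numeric vectors), and a one-row `summary` tibble with
#'   the means and the improvement flag.
#' @export
coupled_prediction_experiment <- function(coupling = 0.8, n_subjects = 17,
                                          n_regions = 30, n_samples = 64800,
                                          sampling_rate = 50,
                                          band = c(8, 13),
                                          subject_dev = 0.8,
                                          deviation_rank = 2,
                                          deviation_dof = 8,
                                          epoch_seconds = 0.72,
                                          grid_fractions = c(0.2, 0.4,
                                                             0.6, 0.8),
                                          n_perm = 10, seed = 1L) {
  sp <- synthetic_spec(n_subjects = n_subjects, n_regions = n_regions,
                       n_samples = n_samples,
                       sampling_rate = sampling_rate,
                       bands = list(band = band), coupling = coupling,
                       subject_dev = subject_dev,
                       deviation_rank = deviation_rank,
                       deviation_dof = deviation_dof,
                       epoch_seconds = epoch_seconds, seed = seed)
  sim <- make_coupled_timeseries(sp, carriers = FALSE)
  Yc <- lapply(sim$subjects, function(s) {
    normalized_precision(shrinkage_covariance(s$slow))
  })
  Xc <- lapply(sim$subjects, function(s) {
    normalized_precision(shrinkage_covariance(s$envelopes$band))
  })
  X <- edge_dataset_from_connectomes(Xc, modality = "fast")
  Y <- edge_dataset_from_connectomes(Yc, modality = "slow")
  p <- ncol(X$matrix)
  grid <- tibble(c1 = pmax(1, grid_fractions * sqrt(p)),
                 c2 = pmax(1, grid_fractions * sqrt(p)))
  rep_all <- loo_predict(X, Y, grid = grid, n_perm = n_perm,
                         seed = derive_seeds(seed, 2)[2])
  loo <- rep_all[rep_all$direction == "y_from_x", , drop = FALSE]
  Ymats <- lapply(Yc, function(cn) cn$matrix)
  S <- length(Ymats)
  baseline_mean <- vapply(seq_len(S), function(s) {
    gm <- Reduce(`+`, Ymats[-s]) / (S - 1)
    diag(gm) <- 1
    dai(gm, Ymats[[s]])
  }, numeric(1))
  baseline_pairwise <- vapply(seq_len(S), function(s) {
    mean(vapply(setdiff(seq_len(S), s), function(j) {
      dai(Ymats[[s]], Ymats[[j]])
    }, numeric(1)))
  }, numeric(1))
  summary <- tibble(
    coupling = coupling,
    loo_mean = mean(loo$distance, na.rm = TRUE),
    baseline_mean = mean(baseline_mean),
    baseline_pairwise = mean(baseline_pairwise),
    n_repaired = sum(loo$repaired, na.rm = TRUE),
    improved = mean(loo$distance, na.rm = TRUE) < mean(baseline_mean))
  list(loo = loo, baseline_mean = baseline_mean,
       baseline_pairwise = baseline_pairwise, summary = summary)
}
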