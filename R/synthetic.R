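#' Specification of a synthetic paired-modality recording
#'
#' Bundles the parameters of the synthetic-data generator: a cohort of
#' subjects, each with a slow "hemodynamic-like" modality and a set of
#' narrowband "electrophysiology-like" signals whose amplitude envelopes
#' carry a subject-specific covariance structure partially shared with the
#' slow modality.
#'
#' @param n_subjects number of subjects (default 17, mirroring a typical
#'   simultaneous-recording cohort).
#' @param n_regions number of brain regions (default 30, a desk-scale
#'   network size).
#' @param n_samples number of time samples per subject.
#' @param sampling_rate sampling rate in Hz.
#' @param bands named list of `c(low, high)` band edges in Hz; defaults to
#'   the five canonical bands delta (1-4), theta (4-8), alpha (8-13),
#'   beta (13-30), gamma (30-70).
#' @param coupling fraction in \[0, 1\] of the envelope covariance shared
#'   with the slow modality: 1 means both modalities are governed by the
#'   same subject covariance, 0 means they are independent.
#' @param subject_dev scale (>= 0) of the per-subject deviation: each
#'   subject's covariance is the common base transported by the
#'   congruence \eqn{(I + subject\_dev \cdot W_s) B (I + subject\_dev
#'   \cdot W_s)^\top} with \eqn{W_s} a low-rank Wishart draw.
#' @param deviation_rank rank of the shared deviation subspace: every
#'   subject's Wishart deviation is drawn with a common rank-deficient
#'   scale matrix, so individual differences across the cohort occupy a
#'   common low-dimensional subspace (as individual differences in real
#'   cohorts do) instead of mutually orthogonal random directions.
#'   Default `min(3, n_regions - 1)`.
#' @param deviation_dof degrees of freedom of each subject's deviation
#'   draw within that subspace.
#' @param env_log_sd standard-deviation scale of the log-envelope process.
#' @param epoch_seconds epoch (repetition-time) duration in seconds used to
#'   derive the slow modality's sampling interval; default 2.16.
#' @param seed integer seed; all generator randomness derives from it.
#' @return An object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(n_subjects = 17, n_regions = 30,
                           n_samples = 21600, sampling_rate = 250,
                           bands = default_bands(),
                           coupling = 0.8, subject_dev = 0.3,
                           deviation_rank = NULL, deviation_dof = 4,
                           env_log_sd = 0.25, epoch_seconds = 2.16,
                           seed = 1L) {
  stopifnot(n_subjects >= 1, n_regions >= 2)
  if (n_samples < 1) abort("`n_samples` must be positive (empty series rejected).")
  if (coupling < 0 || coupling > 1) abort("`coupling` must lie in [0, 1].")
  if (subject_dev < 0) abort("`subject_dev` must be non-negative.")
  bands <- validate_bands(bands, sampling_rate)
  if (epoch_seconds <= 0) abort("`epoch_seconds` must be positive.")
  if (n_samples < 10 * n_regions) {
    warn("n_samples < 10 * n_regions; covariance estimates will be noisy.")
  }
  deviation_rank <- deviation_rank %||% min(3L, n_regions - 1L)
  if (deviation_rank < 1 || deviation_rank > n_regions) {
    abort("`deviation_rank` must lie in [1, n_regions].")
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_regions = as.integer(n_regions),
         n_samples = as.integer(n_samples),
         sampling_rate = sampling_rate, bands = bands,
         coupling = coupling, subject_dev = subject_dev,
         deviation_rank = as.integer(deviation_rank),
         deviation_dof = as.integer(deviation_dof),
         env_log_sd = env_log_sd, epoch_seconds = epoch_seconds,
         seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' The five canonical frequency bands
#'
#' @return Named list of `c(low, high)` Hz pairs: delta 1-4, theta 4-8,
#'   alpha 8-13, beta 13-30, gamma 30-70.
#' @export
default_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 30), gamma = c(30, 70))
}

validate_bands <- function(bands, sampling_rate) {
  if (!is.list(bands) || is.null(names(bands)) || any(names(bands) == "")) {
    abort("`bands` must be a named list of c(low, high) pairs.")
  }
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2 || b[1] <= 0 || b[1] >= b[2]) {
      abort(sprintf("Band '%s' must satisfy 0 < low < high.", nm))
    }
    if (b[2] >= sampling_rate / 2) {
      abort(sprintf("Band '%s' upper edge %.3g Hz is at or above Nyquist (%.3g Hz).",
                    nm, b[2], sampling_rate / 2))
    }
  }
  bands
}

# Random SPD matrix with unit diagonal: a correlation-like base structure.
# Drawn with 4x oversampling so the spectrum stays well away from zero
# (eigenvalues roughly in [0.25, 2.25] before normalization); near-singular
# base covariances would make the true precision matrices ill-conditioned
# and the geodesic comparisons numerically brittle.
random_base_spd <- function(n_regions) {
  A <- matrix(rnorm(n_regions * 4L * n_regions), 4L * n_regions, n_regions)
  S <- crossprod(A) / (4L * n_regions)
  d <- 1 / sqrt(diag(S))
  symmetrize(S * tcrossprod(d))
}

# Gaussian series (t x r) with exact cross-sectional covariance C at
# stationarity: iid normals smoothed over time with an L2-normalized
# Gaussian kernel (smoothing preserves the cross-column covariance up to
# the kernel's L2 norm), then colored by chol(C).
smooth_gaussian_series <- function(n_samples, C, smooth_samples) {
  r <- nrow(C)
  half <- max(1L, ceiling(3 * smooth_samples))
  k <- exp(-0.5 * ((-half:half) / smooth_samples)^2)
  k <- k / sqrt(sum(k^2))
  # FFT circular convolution at a 2-3-5-smooth length; the wrap-around
  # contamination is confined to the first 2*half rows, which are dropped.
  ntot <- stats::nextn(n_samples + 2L * half, c(2L, 3L, 5L))
  Z <- matrix(rnorm(ntot * r), ncol = r)
  kf <- fft(c(k, numeric(ntot - length(k))))
  Zs <- Re(stats::mvfft(stats::mvfft(Z) * kf, inverse = TRUE)) / ntot
  Zs <- Zs[(2L * half + 1L):(2L * half + n_samples), , drop = FALSE]
  Zs %*% chol(C)
}

# Narrowband unit-envelope carriers (one column per region): band-filtered
# white noise divided by its own analytic-signal magnitude, so the only
# amplitude modulation in the synthetic band series is the planted
# envelope.
unit_envelope_carriers <- function(n_samples, n_regions, band,
                                   sampling_rate) {
  pad <- 1000L
  X <- matrix(rnorm((n_samples + 2L * pad) * n_regions), ncol = n_regions)
  bf <- signal::butter(2, band / (sampling_rate / 2), type = "pass")
  Yf <- butter_filter_cols(X, bf)
  Yb <- butter_filter_cols(Yf[nrow(Yf):1L, , drop = FALSE], bf)
  Y <- Yb[nrow(Yb):1L, , drop = FALSE][(pad + 1L):(pad + n_samples), ,
                                       drop = FALSE]
  env <- Mod(analytic_signal(Y))
  Y / pmax(env, 1e-12)
}

#' Generate coupled paired-modality region time series
#'
#' For each subject a covariance \eqn{C_s = A_s B A_s^\top} governs the
#' slow modality, where \eqn{B} is a fixed well-conditioned base and
#' \eqn{A_s = I + dev \cdot W_s} carries the subject's individual
#' deviation: \eqn{W_s} is a Wishart draw whose (rank-deficient) scale
#' matrix spans a cohort-shared low-dimensional subspace. The congruence
#' form guarantees positive definiteness, makes the between-subject
#' geodesic distance scale monotonically with `subject_dev`, and confines
#' individual differences to a common subspace so they are learnable
#' across subjects. The slow modality is a temporally smoothed Gaussian
#' series with cross-sectional covariance exactly \eqn{C_s}. Each band's
#' log-envelope is an independent smoothed Gaussian series with covariance
#' \eqn{coupling \cdot C_s + (1 - coupling) \cdot Q_{s,b}}, where
#' \eqn{Q_{s,b}} is an independently structured SPD matrix (its own base
#' and deviation subspace), exponentiated and used to amplitude-modulate
#' a unit-envelope narrowband carrier. Carriers and envelopes are drawn
#' independently across bands, so inter-band envelope correlations are
#' low by construction.
#'
#' @param spec a [synthetic_spec()].
#' @param carriers generate the narrowband carrier signals and the
#'   amplitude-modulated band series (`TRUE`, default). With `FALSE` only
#'   the envelopes and the slow modality are produced, which is
#'   substantially cheaper when downstream analysis works at the
#'   envelope/connectome level.
#' @return A list with `subjects` (per subject: `slow` and named `bands`
#'   [region_ts()] objects, `envelopes` with the true modulators, and
#'   `covariance` = \eqn{C_s}), plus the `spec` and the base matrix `base`.
#' @export
make_coupled_timeseries <- function(spec, carriers = TRUE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    B <- random_base_spd(spec$n_regions)
    B_ind <- random_base_spd(spec$n_regions)   # base of the uncoupled part
    F_shared <- deviation_basis(spec$n_regions, spec$deviation_rank)
    F_ind <- deviation_basis(spec$n_regions, spec$deviation_rank)
    labels <- sprintf("R%02d", seq_len(spec$n_regions))
    # Slow modality lives at epoch (TR) resolution: one sample per epoch.
    spe <- round(spec$epoch_seconds * spec$sampling_rate)
    slow_len <- max(2L, floor(spec$n_samples / spe))
    env_smooth <- spec$sampling_rate / 4     # ~0.25 s envelope timescale
    subjects <- lapply(seq_len(spec$n_subjects), function(s) {
      Cs <- subject_covariance(B, F_shared, spec$subject_dev,
                               spec$deviation_dof)
      slow <- smooth_gaussian_series(slow_len, Cs, 0.75)
      bands <- list(); envs <- list()
      for (nm in names(spec$bands)) {
        Qs <- subject_covariance(B_ind, F_ind, spec$subject_dev,
                                 spec$deviation_dof)
        Cenv <- symmetrize(spec$coupling * Cs + (1 - spec$coupling) * Qs)
        G <- smooth_gaussian_series(spec$n_samples, Cenv, env_smooth)
        A <- exp(spec$env_log_sd * G)
        if (carriers) {
          cr <- unit_envelope_carriers(spec$n_samples, spec$n_regions,
                                       spec$bands[[nm]], spec$sampling_rate)
          bands[[nm]] <- region_ts(A * cr, spec$sampling_rate, labels,
                                   subject_id = s, modality = "banded",
                                   band = nm)
        }
        envs[[nm]] <- region_ts(A, spec$sampling_rate, labels,
                                subject_id = s, modality = "envelope", band = nm)
      }
      list(slow = region_ts(slow, 1 / spec$epoch_seconds, labels,
                            subject_id = s, modality = "slow"),
           bands = bands, envelopes = envs, covariance = Cs)
    })
    list(subjects = subjects, spec = spec, base = B)
  })
}

# Shared deviation basis: orthonormal columns, so the subject deviation
# W = F G G' F' has unit-scale eigenvalues within the shared subspace and
# the congruence factor I + dev * W stays well conditioned.
deviation_basis <- function(n_regions, rank) {
  M <- matrix(rnorm(n_regions * rank), n_regions, rank)
  qr.Q(qr(M))
}

# Subject covariance C_s = A_s B A_s' with A_s = I + dev * W_s and W_s a
# Wishart draw with the (rank-deficient) scale F F' / dof. The congruence
# form keeps C_s SPD for any dev >= 0, confines individual differences to
# the cohort's shared deviation subspace, and makes the affine-invariant
# distance between subjects scale monotonically with dev (additive
# deviations do not: the metric is relative, so inflating both matrices
# by a common additive term leaves their geodesic separation unchanged).
subject_covariance <- function(B, F_basis, subject_dev, dof,
                               max_tries = 5L) {
  for (i in seq_len(max_tries)) {
    G <- matrix(rnorm(ncol(F_basis) * dof, sd = 1 / sqrt(dof)),
                ncol(F_basis), dof)
    W <- tcrossprod(F_basis %*% G)
    A <- diag(nrow(B)) + subject_dev * W
    Cs <- symmetrize(A %*% B %*% A)
    if (check_spd(Cs)$spd) return(Cs)
  }
  abort(sprintf("Failed to draw an SPD subject covariance in %d attempts.",
                max_tries))
}

#' Generate paired edge datasets with a planted sparse linkage
#'
#' Direct fixture for sparse canonical correlation: two subjects-by-edges
#' matrices sharing a single latent score along sparse directions,
#' \deqn{X = t u_*^\top + E, \quad Y = t v_*^\top + F,}
#' with \eqn{t \sim N(0, score\_sd^2)} per subject and iid
#' \eqn{N(0, noise\_sd^2)} noise. The planted unit-norm sparse vectors are
#' returned so recovery can be scored against ground truth.
#'
#' @param n_subjects number of rows (>= 3).
#' @param p,q numbers of columns of `X` and `Y`.
#' @param support size of the planted support in each block (>= 1, <=
#'   `min(p, q)`).
#' @param score_sd standard deviation of the shared latent score.
#' @param noise_sd standard deviation of the additive noise.
#' @param seed integer seed.
#' @return List with edge datasets `X`, `Y` and `linkage` (fields
#'   `u_star`, `v_star`, `scores`, `noise_sd`).
#' @export
make_linked_edge_datasets <- function(n_subjects, p, q, support,
                                      score_sd = 1, noise_sd = 0.1,
                                      seed = 1L) {
  if (support < 1) abort("`support` must be at least 1.")
  if (support > min(p, q)) abort("`support` cannot exceed min(p, q).")
  if (n_subjects < 3) abort("Need at least 3 subjects.")
  with_seed(seed, {
    u <- numeric(p); v <- numeric(q)
    su <- sample.int(p, support); sv <- sample.int(q, support)
    u[su] <- rnorm(support); v[sv] <- rnorm(support)
    # avoid degenerate zero draws
    u[su] <- u[su] + sign(u[su] + (u[su] == 0)) * 0.5
    v[sv] <- v[sv] + sign(v[sv] + (v[sv] == 0)) * 0.5
    u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
    t_score <- rnorm(n_subjects, sd = score_sd)
    X <- tcrossprod(t_score, u) + matrix(rnorm(n_subjects * p, sd = noise_sd),
                                         n_subjects, p)
    Y <- tcrossprod(t_score, v) + matrix(rnorm(n_subjects * q, sd = noise_sd),
                                         n_subjects, q)
    list(X = edge_dataset(X, modality = "x"),
         Y = edge_dataset(Y, modality = "y"),
         linkage = list(u_star = u, v_star = v, scores = t_score,
                        support_x = sort(su), support_y = sort(sv),
                        noise_sd = noise_sd))
  })
}

#' Draw pairs of random Wishart SPD matrices
#'
#' Each matrix is drawn from a Wishart distribution with `dof` degrees of
#' freedom and scale `diag(order) / dof`, so its expectation is the
#' identity; as `dof` grows the draws concentrate at the identity and the
#' within-pair distance shrinks.
#'
#' @param order matrix order.
#' @param dof degrees of freedom (>= `order` for invertibility).
#' @param n_pairs number of pairs.
#' @param seed integer seed.
#' @return List of `n_pairs` two-element lists of SPD matrices.
#' @export
make_wishart_pairs <- function(order, dof, n_pairs, seed = 1L) {
  if (dof < order) {
    abort(sprintf("`dof` (%d) must be at least the matrix order (%d).",
                  as.integer(dof), as.integer(order)))
  }
  with_seed(seed, {
    draws <- rWishart(2L * n_pairs, df = dof, Sigma = diag(order) / dof)
    lapply(seq_len(n_pairs), function(i) {
      list(symmetrize(draws[, , 2L * i - 1L]), symmetrize(draws[, , 2L * i]))
    })
  })
}

#' Standard atlas region labels
#'
#' The 68 cortical labels of the Desikan-Killiany parcellation (34 per
#' hemisphere), optionally preceded by 14 subcortical labels (7 per
#' hemisphere), matching the convention of placing subcortical regions in
#' the top-left corner of the connectivity matrix.
#'
#' @param include_subcortical include the 14 subcortical labels first.
#' @return Character vector of 68 or 82 unique labels.
#' @export
region_label_fixture <- function(include_subcortical = FALSE) {
  cortical <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal",
    "temporalpole", "transversetemporal")
  subcortical <- c("thalamus", "caudate", "putamen", "pallidum",
                   "hippocampus", "amygdala", "accumbens")
  both <- function(x) c(paste0("lh.", x), paste0("rh.", x))
  labels <- both(cortical)
  if (include_subcortical) labels <- c(both(subcortical), labels)
  labels
}
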