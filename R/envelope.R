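#' Region-by-time multivariate series
#'
#' Container for one subject's regional signals in one modality (and
#' optionally one frequency band): a time-by-regions numeric matrix with a
#' sampling rate and region labels.
#'
#' @param values numeric matrix, time samples in rows, regions in columns.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param labels character vector of region names, one per column.
#' @param subject_id,modality,band optional provenance tags.
#' @return An object of class `region_ts`.
#' @export
region_ts <- function(values, sampling_rate, labels = colnames(values),
                      subject_id = NULL, modality = NULL, band = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || nrow(values) < 1) {
    abort("`values` must be a non-empty numeric matrix (time x regions).")
  }
  if (anyNA(values)) abort("`values` must not contain missing values.")
  if (sampling_rate <= 0) abort("`sampling_rate` must be positive.")
  if (is.null(labels)) labels <- sprintf("R%02d", seq_len(ncol(values)))
  if (length(labels) != ncol(values)) {
    abort("`labels` length must equal the number of regions (columns).")
  }
  colnames(values) <- labels
  structure(list(values = values, sampling_rate = sampling_rate,
                 labels = labels, subject_id = subject_id,
                 modality = modality, band = band),
            class = "region_ts")
}

#' @export
print.region_ts <- function(x, ...) {
  cat(sprintf("<region_ts> %d samples x %d regions @ %g Hz", nrow(x$values),
              ncol(x$values), x$sampling_rate))
  tags <- c(subject = x$subject_id, modality = x$modality, band = x$band)
  if (length(tags)) cat("  [", paste(names(tags), tags, sep = "=", collapse = ", "), "]")
  cat("\n")
  invisible(x)
}

#' @export
dim.region_ts <- function(x) dim(x$values)

as_region_values <- function(ts) {
  if (inherits(ts, "region_ts")) ts$values else as.matrix(ts)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters every region's signal with a second-order Butterworth band-pass
#' applied forward and then reverse, so the net filter has zero phase and
#' the squared magnitude response of the single-pass design. To bound edge
#' transients the signal is extended by reflection (one epoch length by
#' default) before filtering and trimmed afterwards.
#'
#' @param ts a [region_ts()].
#' @param band `c(low, high)` band edges in Hz, both below Nyquist.
#' @param band_name optional name recorded on the output.
#' @param pad_seconds reflection padding length in seconds (default 2.16,
#'   one epoch).
#' @return A `region_ts` of the same shape, band tagged.
#' @export
bandpass <- function(ts, band, band_name = NULL, pad_seconds = 2.16) {
  X <- as_region_values(ts)
  fs <- if (inherits(ts, "region_ts")) ts$sampling_rate else
    abort("Provide a region_ts so the sampling rate is known.")
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2]) {
    abort("`band` must be c(low, high) with 0 < low < high.")
  }
  if (band[2] >= fs / 2) {
    abort(sprintf("Band edge %.3g Hz is at or above Nyquist (%.3g Hz).",
                  band[2], fs / 2))
  }
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  n <- nrow(X)
  pad <- min(max(1L, round(pad_seconds * fs)), n - 1L)
  top <- 2 * X[rep(1L, pad), , drop = FALSE] -
    X[(pad + 1L):2L, , drop = FALSE]
  bot <- 2 * X[rep(n, pad), , drop = FALSE] -
    X[(n - 1L):(n - pad), , drop = FALSE]
  Xp <- rbind(top, X, bot)
  Yf <- butter_filter_cols(Xp, bf)
  Yb <- butter_filter_cols(Yf[nrow(Yf):1L, , drop = FALSE], bf)
  Y <- Yb[nrow(Yb):1L, , drop = FALSE][(pad + 1L):(pad + n), , drop = FALSE]
  region_ts(Y, fs, ts$labels, ts$subject_id, ts$modality,
            band = band_name %||% ts$band)
}

# Apply an ARMA digital filter down every column with zero initial
# conditions, in C via stats::filter (convolution part, then recursion).
butter_filter_cols <- function(X, bf) {
  b <- bf$b; a <- bf$a
  nb <- length(b)
  Xp <- rbind(matrix(0, nb - 1L, ncol(X)), X)
  tmp <- stats::filter(Xp, b, method = "convolution", sides = 1)
  tmp <- tmp[-seq_len(nb - 1L), , drop = FALSE]
  out <- stats::filter(tmp, -a[-1], method = "recursive")
  matrix(as.numeric(out), nrow(X), ncol(X))
}

# Analytic signal via the frequency-domain construction: zero out negative
# frequencies, double positive ones. Accepts a vector or a matrix
# (column-wise, through mvfft).
analytic_signal <- function(x) {
  vec <- !is.matrix(x)
  X <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(X)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  A <- stats::mvfft(stats::mvfft(X) * h, inverse = TRUE) / n
  if (vec) as.complex(A[, 1]) else A
}

#' Hilbert amplitude envelope
#'
#' Per region, the magnitude of the analytic signal (signal plus i times
#' its Hilbert transform): the instantaneous amplitude of a narrowband
#' signal.
#'
#' @param ts a [region_ts()] with at least 8 samples.
#' @return A `region_ts` of non-negative envelope samples, same shape.
#' @export
hilbert_envelope <- function(ts) {
  X <- as_region_values(ts)
  if (nrow(X) < 8) abort("Need at least 8 samples for a meaningful envelope.")
  E <- Mod(analytic_signal(X))
  region_ts(E, ts$sampling_rate, ts$labels, ts$subject_id,
            modality = "envelope", band = ts$band)
}

#' Segment a series into consecutive fixed-length epochs
#'
#' Epochs have `round(epoch_seconds * sampling_rate)` samples; a trailing
#' partial epoch is discarded.
#'
#' @param ts a [region_ts()].
#' @param epoch_seconds epoch duration in seconds.
#' @return A tibble with columns `epoch`, `start`, `end` (sample indices,
#'   inclusive); the attribute `samples_per_epoch` records the epoch
#'   length.
#' @export
segment_epochs <- function(ts, epoch_seconds) {
  fs <- ts$sampling_rate
  spe <- round(epoch_seconds * fs)
  if (spe < 1) abort("`epoch_seconds * sampling_rate` must be at least 1.")
  n <- nrow(ts$values)
  k <- floor(n / spe)
  out <- tibble(epoch = seq_len(k),
                start = (seq_len(k) - 1L) * spe + 1L,
                end = seq_len(k) * spe)
  attr(out, "samples_per_epoch") <- spe
  out
}

#' Epoch-averaged envelope series (AWE)
#'
#' Averages the envelope within each epoch, producing one sample per
#' retained epoch so the fast modality's envelope series has time samples
#' matching the slow modality's. The first `drop_first` epochs are
#' excluded, mirroring the exclusion of initial volumes in the slow
#' modality's preprocessing.
#'
#' @param envelope a [region_ts()] of envelope samples.
#' @param epoch_seconds epoch duration in seconds.
#' @param drop_first number of initial epochs to discard (default 5).
#' @return A `region_ts` with one sample per retained epoch, sampled at
#'   `1 / epoch_seconds` Hz.
#' @export
awe_series <- function(envelope, epoch_seconds, drop_first = 5) {
  ep <- segment_epochs(envelope, epoch_seconds)
  if (nrow(ep) <= drop_first) {
    abort(sprintf("Only %d epochs available; cannot drop %d and retain any.",
                  nrow(ep), drop_first))
  }
  keep <- ep[ep$epoch > drop_first, , drop = FALSE]
  X <- envelope$values
  M <- do.call(rbind, lapply(seq_len(nrow(keep)), function(i) {
    colMeans(X[keep$start[i]:keep$end[i], , drop = FALSE])
  }))
  region_ts(M, 1 / epoch_seconds, envelope$labels, envelope$subject_id,
            modality = "awe", band = envelope$band)
}

#' Full-resolution envelope series with initial epochs removed (WTS)
#'
#' Keeps the envelope at its native resolution but removes the samples of
#' the first `drop_first` epochs; connectivity is then estimated at the
#' fast modality's own time resolution.
#'
#' @inheritParams awe_series
#' @param include_partial keep the trailing partial epoch's samples
#'   (`TRUE`) or trim to whole epochs (`FALSE`, default, consistent with
#'   [segment_epochs()]).
#' @return A `region_ts` at the original sampling rate.
#' @export
wts_series <- function(envelope, epoch_seconds, drop_first = 5,
                       include_partial = FALSE) {
  ep <- segment_epochs(envelope, epoch_seconds)
  if (nrow(ep) <= drop_first) {
    abort(sprintf("Only %d epochs available; cannot drop %d and retain any.",
                  nrow(ep), drop_first))
  }
  first <- if (drop_first > 0) ep$end[drop_first] + 1L else 1L
  last <- if (include_partial) nrow(envelope$values) else ep$end[nrow(ep)]
  region_ts(envelope$values[first:last, , drop = FALSE],
            envelope$sampling_rate, envelope$labels, envelope$subject_id,
            modality = "wts", band = envelope$band)
}
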