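# Shared fixtures, built in code.

random_spd <- function(n, jitter = 1) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n + jitter * diag(n)
}

# Independent evaluation of the affine-invariant distance through the
# explicit matrix logarithm of G^{-1/2} P G^{-1/2}.
dai_matrix_log <- function(P, G) {
  eg <- eigen(G, symmetric = TRUE)
  Ginvhalf <- eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
  W <- Ginvhalf %*% P %*% Ginvhalf
  ew <- eigen((W + t(W)) / 2, symmetric = TRUE)
  L <- ew$vectors %*% (log(ew$values) * t(ew$vectors))
  sqrt(sum(L^2))
}

# A sinusoidal region_ts fixture.
tone_ts <- function(freq, fs = 250, seconds = 10, amp = 1) {
  t <- seq(0, seconds - 1 / fs, by = 1 / fs)
  region_ts(cbind(tone = amp * sin(2 * pi * freq * t)), fs)
}

# Magnitude response of the zero-phase (forward + reverse) digital filter
# with coefficients b, a at frequency f: |H(e^{i 2 pi f / fs})|^2.
butter_mag2 <- function(bf, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  H <- sum(bf$b * z^(seq_along(bf$b) - 1)) / sum(bf$a * z^(seq_along(bf$a) - 1))
  Mod(H)^2
}
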