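# Internal helpers shared across modules.

# Symmetry check with an absolute tolerance (our matrices are small enough
# that a relative scheme buys nothing).
is_symmetric_tol <- function(M, tol = 1e-10) {
  is.matrix(M) && nrow(M) == ncol(M) && max(abs(M - t(M))) <= tol
}

assert_symmetric <- function(M, tol = 1e-8, arg = "M") {
  if (!is.matrix(M) || !is.numeric(M)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg))
  }
  if (nrow(M) != ncol(M)) {
    abort(sprintf("`%s` must be square, got %d x %d.", arg, nrow(M), ncol(M)))
  }
  if (max(abs(M - t(M))) > tol) {
    abort(sprintf("`%s` is not symmetric within tolerance %g.", arg, tol))
  }
  invisible(M)
}

# Force exact symmetry after numerically symmetric operations (inversion,
# eigen reconstruction) so downstream tolerance checks never trip.
symmetrize <- function(M) (M + t(M)) / 2

# Deterministic child seeds: derive a stream of well-separated 32-bit seeds
# from a single user seed so that independent stages never share a stream.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  (as.integer(seed) + 1000003L * seq_len(n)) %% 2147483647L
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(code)
}
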