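#' Concatenate per-band edge datasets column-wise
#'
#' Stacks the columns of one edge dataset per frequency band into a single
#' wide predictor block, recording each band's column offset. Fitting a
#' single sparse model on the concatenated block means one pair of
#' sparsity parameters governs all bands, so selection probabilities are
#' comparable across bands.
#'
#' @param datasets named list of [edge_dataset()]s with identical subject
#'   counts (and edge indices, when present).
#' @return An [edge_dataset()] whose attribute `band_offsets` is a tibble
#'   with `band`, `start`, `end` column ranges.
#' @export
concat_bands <- function(datasets) {
  stopifnot(is.list(datasets), length(datasets) >= 1)
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    names(datasets) <- paste0("band", seq_along(datasets))
  }
  ns <- vapply(datasets, function(d) nrow(as_edge_matrix(d)), integer(1))
  if (length(unique(ns)) != 1) {
    abort("All per-band datasets must have the same number of subjects.")
  }
  idx0 <- datasets[[1]]$edge_index
  for (d in datasets[-1]) {
    if (!is.null(idx0) && !is.null(d$edge_index) &&
        !identical(idx0[c("region_i", "region_j")],
                   d$edge_index[c("region_i", "region_j")])) {
      abort("Edge indices differ across bands.")
    }
  }
  mats <- lapply(datasets, as_edge_matrix)
  widths <- vapply(mats, ncol, integer(1))
  ends <- cumsum(widths)
  offsets <- tibble(band = names(datasets),
                    start = unname(c(1L, head(ends, -1) + 1L)),
                    end = unname(ends))
  out <- edge_dataset(do.call(cbind, mats), band = "concatenated",
                      modality = datasets[[1]]$modality,
                      labels = datasets[[1]]$labels)
  out$band_offsets <- offsets
  out$edge_index <- idx0
  out
}

#' Randomized-Lasso stability selection for sparse CCA
#'
#' Repeatedly refits the sparse CCA after perturbing the penalty of every
#' column: per repetition each column of both blocks is rescaled by a
#' weight drawn uniformly from `weights` (0.5 or 1 by default), which is
#' equivalent to randomly tightening that column's effective L1 penalty.
#' A column counts as selected when its coefficient is nonzero in any
#' retained component. The selection probability of a connection is the
#' fraction of repetitions in which it was selected; connections that are
#' genuinely informative survive the perturbations, which controls false
#' positives without committing to a single sparsity level.
#'
#' @param X concatenated predictor block (see [concat_bands()]) or any
#'   [edge_dataset()]/matrix.
#' @param Y response block.
#' @param c1,c2 L1 bounds, typically chosen once by [select_penalties()]
#'   and held fixed across repetitions.
#' @param n_reps number of randomized repetitions (>= 1).
#' @param K components per fit (default 1).
#' @param weights the weight set for the random column rescaling.
#' @param seed integer seed.
#' @return An object of class `selection_profile` with per-column
#'   selection probabilities for both blocks, the band offsets (when `X`
#'   carries them), and the run parameters. See [top_selection()],
#'   [tidy.selection_profile()].
#' @export
randomized_scca <- function(X, Y, c1, c2, n_reps = 1000, K = 1,
                            weights = c(0.5, 1), seed = 1L) {
  if (n_reps < 1) abort("`n_reps` must be at least 1.")
  Xm <- as_edge_matrix(X); Ym <- as_edge_matrix(Y)
  p <- ncol(Xm); q <- ncol(Ym)
  counts_x <- numeric(p); counts_y <- numeric(q)
  seeds <- derive_seeds(seed, n_reps)
  for (r in seq_len(n_reps)) {
    draws <- with_seed(seeds[r], list(
      wx = sample(weights, p, replace = TRUE),
      wy = sample(weights, q, replace = TRUE)))
    fit <- scca_fit(sweep(Xm, 2, draws$wx, `*`),
                    sweep(Ym, 2, draws$wy, `*`), c1, c2, K = K)
    if (fit$K > 0) {
      counts_x <- counts_x + (rowSums(abs(fit$U)) > 0)
      counts_y <- counts_y + (rowSums(abs(fit$V)) > 0)
    }
  }
  structure(
    list(x_probability = counts_x / n_reps,
         y_probability = counts_y / n_reps,
         n_reps = as.integer(n_reps), c1 = c1, c2 = c2, K = K,
         weight_set = weights, seed = seed,
         band_offsets = if (inherits(X, "edge_dataset")) X$band_offsets else NULL,
         edge_index = if (inherits(X, "edge_dataset")) X$edge_index else NULL),
    class = "selection_profile")
}

#' @export
print.selection_profile <- function(x, ...) {
  cat(sprintf("<selection_profile> %d X-columns, %d Y-columns, %d repetitions\n",
              length(x$x_probability), length(x$y_probability), x$n_reps))
  cat(sprintf("  penalties c1 = %.3f, c2 = %.3f; weights {%s}\n",
              x$c1, x$c2, paste(x$weight_set, collapse = ", ")))
  invisible(x)
}

block_table <- function(profile) {
  p <- length(profile$x_probability)
  if (!is.null(profile$band_offsets)) {
    off <- profile$band_offsets
    blocks <- lapply(seq_len(nrow(off)), function(i) {
      tibble(block = off$band[i], column = off$start[i]:off$end[i],
             edge = seq_len(off$end[i] - off$start[i] + 1L),
             probability = profile$x_probability[off$start[i]:off$end[i]])
    })
    xs <- dplyr::bind_rows(blocks)
  } else {
    xs <- tibble(block = "x", column = seq_len(p), edge = seq_len(p),
                 probability = profile$x_probability)
  }
  ys <- tibble(block = "y", column = seq_along(profile$y_probability),
               edge = seq_along(profile$y_probability),
               probability = profile$y_probability)
  dplyr::bind_rows(xs, ys)
}

#' Top connections by selection probability
#'
#' Within each band block of the predictor side (and for the response
#' block), ranks columns by selection probability and keeps the top
#' `ceiling(fraction * block_size)`; ties are broken by edge index.
#'
#' @param profile a [randomized_scca()] result.
#' @param fraction fraction of each block to keep, in (0, 1\].
#' @return Tibble with `block`, `edge`, `probability`, `rank`.
#' @export
top_selection <- function(profile, fraction) {
  stopifnot(inherits(profile, "selection_profile"))
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1].")
  tab <- block_table(profile)
  out <- lapply(split(tab, tab$block), function(b) {
    k <- ceiling(fraction * nrow(b))
    ord <- order(-b$probability, b$edge)
    sel <- b[ord[seq_len(k)], , drop = FALSE]
    sel$rank <- seq_len(k)
    sel
  })
  dplyr::bind_rows(out)
}
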