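#' Tidy a sparse CCA fit
#'
#' One row per nonzero coefficient: which block (`"x"`/`"y"`), component,
#' column index and coefficient value.
#'
#' @param x an [scca_fit()].
#' @param keep_zeros include zero coefficients too.
#' @param ... unused.
#' @return A tibble with `block`, `component`, `column`, `estimate`.
#' @export
tidy.scca_fit <- function(x, keep_zeros = FALSE, ...) {
  one <- function(M, block) {
    rows <- lapply(seq_len(ncol(M)), function(k) {
      tibble(block = block, component = k, column = seq_len(nrow(M)),
             estimate = M[, k])
    })
    dplyr::bind_rows(rows)
  }
  out <- dplyr::bind_rows(one(x$U, "x"), one(x$V, "y"))
  if (!keep_zeros) out <- out[out$estimate != 0, , drop = FALSE]
  out
}

#' Glance at a sparse CCA fit
#'
#' @param x an [scca_fit()].
#' @param ... unused.
#' @return One-row tibble with dimensions, penalties, leading canonical
#'   correlation, total nonzero counts and convergence.
#' @export
glance.scca_fit <- function(x, ...) {
  tibble(n = x$n, p = x$p, q = x$q, K = x$K, c1 = x$c1, c2 = x$c2,
         d1 = if (x$K > 0) x$d[1] else NA_real_,
         nonzero_u = sum(x$U != 0), nonzero_v = sum(x$V != 0),
         converged = all(x$converged))
}

#' Tidy an order calibration
#'
#' @param x an [calibrate_order_normalization()] result.
#' @param ... unused.
#' @return Tibble with `order`, `median_distance`, `fitted`.
#' @export
tidy.order_calibration <- function(x, ...) {
  tibble(order = x$orders, median_distance = x$medians,
         fitted = x$intercept + x$slope * x$orders)
}

#' Glance at an order calibration
#'
#' @param x an [calibrate_order_normalization()] result.
#' @param ... unused.
#' @return One-row tibble with `slope`, `intercept`, `r.squared`,
#'   `n_pairs`.
#' @export
glance.order_calibration <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r.squared = x$fit_r2,
         n_pairs = x$n_pairs)
}

#' Tidy a selection profile
#'
#' @param x a [randomized_scca()] result.
#' @param ... unused.
#' @return Tibble with `block` (band name or `"y"`), `edge` (within
#'   block), `column` (within the concatenated matrix) and `probability`.
#' @export
tidy.selection_profile <- function(x, ...) {
  block_table(x)
}

#' Glance at a selection profile
#'
#' @param x a [randomized_scca()] result.
#' @param ... unused.
#' @return One-row tibble with repetition count, penalties and the
#'   maximum selection probabilities per side.
#' @export
glance.selection_profile <- function(x, ...) {
  tibble(n_reps = x$n_reps, c1 = x$c1, c2 = x$c2,
         max_x_probability = max(x$x_probability),
         max_y_probability = max(x$y_probability))
}

#' Box plots of a distance report
#'
#' @param object a `distance_report` tibble (from [loo_predict()],
#'   [intermodal_distance()] or [intersubject_variability()]).
#' @param normalized plot the order-normalized distances when available.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.distance_report <- function(object, normalized = FALSE, ...) {
  ycol <- if (normalized && "normalized_distance" %in% names(object) &&
              !all(is.na(object$normalized_distance))) {
    "normalized_distance"
  } else "distance"
  xcol <- if ("direction" %in% names(object)) "direction"
          else if ("condition" %in% names(object)) "condition" else NULL
  df <- as.data.frame(object)
  if (is.null(xcol)) df$group <- "all" else df$group <- df[[xcol]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data[[ycol]])) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL,
                  y = if (ycol == "distance") "affine-invariant distance"
                      else "normalized distance") +
    ggplot2::theme_minimal()
}

#' Plot an order calibration
#'
#' Median pairwise distance against matrix order with the fitted line.
#'
#' @param object an `order_calibration`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.order_calibration <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$order, y = .data$median_distance)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::labs(x = "matrix order", y = "median distance") +
    ggplot2::theme_minimal()
}

#' Plot a selection profile
#'
#' Selection-probability distributions per block.
#'
#' @param object a `selection_profile`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.selection_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$block, y = .data$probability)) +
    ggplot2::geom_boxplot(fill = "grey85", outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "selection probability") +
    ggplot2::theme_minimal()
}

#' Heatmap of a connectome
#'
#' @param object a [connectome()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.connectome <- function(object, ...) {
  M <- object$matrix
  df <- expand.grid(region_i = factor(object$labels, levels = object$labels),
                    region_j = factor(object$labels, levels = rev(object$labels)))
  df$value <- as.numeric(M[cbind(as.integer(df$region_i),
                                 length(object$labels) + 1L -
                                   as.integer(df$region_j))])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region_i, y = .data$region_j,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "slategray", mid = "white",
                                  high = "salmon") +
    ggplot2::labs(x = NULL, y = NULL, fill = object$kind) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
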