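## broom-style tidiers and plot methods for fitted objects and surfaces.

#' Tidy a trained hierarchy level into one row per coefficient
#'
#' @param x An `rs_trained_level`.
#' @param ... Unused.
#' @return Tibble: `class`, `term` (feature column or "(intercept)"),
#'   `estimate`.
#' @method tidy rs_trained_level
#' @export
tidy.rs_trained_level <- function(x, ...) {
  terms <- c("(intercept)", paste0("f", seq_len(nrow(x$w))))
  est <- rbind(x$b, x$w)
  tibble::tibble(
    class = rep(x$classes, each = length(terms)),
    term = rep(terms, times = length(x$classes)),
    estimate = as.numeric(est))
}

#' One-row training summary of a hierarchy level
#'
#' @param x An `rs_trained_level`.
#' @param ... Unused.
#' @return Tibble: backbone kind, number of classes, epochs, initial and
#'   final training loss.
#' @method glance rs_trained_level
#' @export
glance.rs_trained_level <- function(x, ...) {
  tibble::tibble(kind = x$backbone$spec$kind,
                 n_classes = length(x$classes),
                 n_conv_layers = x$backbone$n_conv_layers,
                 epochs = length(x$loss_trace),
                 loss_first = x$loss_trace[1],
                 loss_final = x$loss_trace[length(x$loss_trace)])
}

#' Tidy a hierarchical model (both levels)
#'
#' @param x An `rs_hierarchical`.
#' @param ... Unused.
#' @return Tibble of per-level glances with a `level` column.
#' @method tidy rs_hierarchical
#' @export
tidy.rs_hierarchical <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(glance(x$level1), level = "coarse"),
    dplyr::mutate(glance(x$level2), level = "base"))
}

#' One-row summary of a hierarchical model
#'
#' @param x An `rs_hierarchical`.
#' @param ... Unused.
#' @return Tibble: backbone kind, registry version, final losses.
#' @method glance rs_hierarchical
#' @export
glance.rs_hierarchical <- function(x, ...) {
  tibble::tibble(kind = x$spec$kind,
                 registry_version = x$registry_version,
                 loss_final_level1 =
                   x$level1$loss_trace[length(x$level1$loss_trace)],
                 loss_final_level2 =
                   x$level2$loss_trace[length(x$level2$loss_trace)])
}

#' Plot the training loss trace of a hierarchy level
#'
#' @param object An `rs_trained_level`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rs_trained_level
#' @export
autoplot.rs_trained_level <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_along(object$loss_trace),
                       loss = object$loss_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "categorical cross-entropy") +
    ggplot2::theme_minimal()
}

#' Plot predicted surface scores as a 2D projection
#'
#' Scatter of grid points in two chosen coordinates, colored by the
#' highest-probability class.
#'
#' @param scored_grid Output of [predict_surface()] (grid plus `prob_*`).
#' @param coords Two coordinate names to plot (default x, y).
#' @return A ggplot object.
#' @export
plot_surface_scores <- function(scored_grid, coords = c("x", "y")) {
  m <- score_matrix(scored_grid)
  scored_grid$top_class <- factor(CLASSES7[max.col(m, ties.method = "first")],
                                  levels = CLASSES7)
  ggplot2::ggplot(scored_grid,
                  ggplot2::aes(.data[[coords[1]]], .data[[coords[2]]],
                               color = .data$top_class)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(color = "top class") +
    ggplot2::theme_minimal()
}
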