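#' Plot a tissue mesh
#'
#' Draws the cell polygons of a tissue, optionally filled by a per-cell
#' statistic (number of neighbors by default).
#'
#' @param object A tissue state.
#' @param fill One of `"n_neighbors"`, `"area"`, `"shape"`, or `"none"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tissue <- function(object, fill = c("n_neighbors", "area", "shape", "none"),
                            ...) {
  fill <- match.arg(fill)
  info <- tidy.tissue(object)
  dfs <- lapply(seq_along(object$cells), function(i) {
    m <- cell_polygon(object, i)
    tibble::tibble(cell = i, x = m[, 1L], y = m[, 2L])
  })
  df <- dplyr::left_join(dplyr::bind_rows(dfs), info[, c("cell", "n_neighbors", "area", "shape")],
                         by = "cell")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, group = .data$cell))
  p <- if (fill == "none") {
    p + ggplot2::geom_polygon(fill = "grey95", colour = "grey20", linewidth = 0.2)
  } else {
    p + ggplot2::geom_polygon(ggplot2::aes(fill = .data[[fill]]),
                              colour = "grey20", linewidth = 0.2) +
      ggplot2::scale_fill_viridis_c()
  }
  p + ggplot2::coord_equal() + ggplot2::theme_void() +
    ggplot2::labs(fill = fill,
                  title = sprintf("t = %.1f, %d cells", object$sim_time,
                                  length(object$cells)))
}

#' Plot a neighbor-number distribution
#'
#' @param f A tibble from [neighbor_distribution()].
#' @param ref Optional reference distribution overlaid as points.
#' @return A ggplot object.
#' @export
plot_neighbor_distribution <- function(f, ref = NULL) {
  p <- ggplot2::ggplot(f, ggplot2::aes(x = .data$n, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.8) +
    ggplot2::labs(x = "number of neighbors", y = "fraction of cells") +
    ggplot2::theme_minimal()
  if (!is.null(ref)) {
    p <- p + ggplot2::geom_point(data = ref, colour = "black", size = 2)
  }
  p
}

#' Plot a Lewis' law fit
#'
#' Mean normalized cell area against neighbor number with the fitted line
#' and the classical reference line \eqn{\bar A_n = (n-2)/4}.
#'
#' @param object A [lewis_law()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lewis_fit <- function(object, ...) {
  df <- tidy.lewis_fit(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$mean_area)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_area - .data$sd_area,
                                        ymax = .data$mean_area + .data$sd_area),
                           width = 0.15, colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::geom_abline(intercept = -0.5, slope = 0.25, linetype = 2) +
    ggplot2::labs(x = "number of neighbors", y = "mean normalized area") +
    ggplot2::theme_minimal()
}

#' Plot observed vs ideal internal-angle distributions
#'
#' @param observed Histogram from [angle_distribution()].
#' @param ideal Histogram from [ideal_angle_distribution()].
#' @return A ggplot object.
#' @export
plot_angle_distribution <- function(observed, ideal = NULL) {
  df <- dplyr::mutate(observed, deg = .data$mid * 180 / pi)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$deg, y = .data$density)) +
    ggplot2::geom_col(fill = "steelblue", width = 4.5) +
    ggplot2::labs(x = "internal vertex angle (degrees)", y = "fraction") +
    ggplot2::theme_minimal()
  if (!is.null(ideal)) {
    p <- p + ggplot2::geom_step(
      data = dplyr::mutate(ideal, deg = .data$mid * 180 / pi),
      direction = "mid", colour = "black")
  }
  p
}
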