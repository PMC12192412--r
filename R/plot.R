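#' Plot a trajectory
#'
#' Draws the tracked x and y coordinate against time, with invalid frames
#' marked along the time axis.
#'
#' @param object An `iris_trajectory`.
#' @param truth Optional ground-truth tibble overlaid as open circles.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.iris_trajectory <- function(object, truth = NULL, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "time_s", "x", "y", "valid"),
    c("x", "y"), names_to = "axis", values_to = "px")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$px)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 1, na.rm = TRUE) +
    ggplot2::geom_rug(data = dplyr::filter(long, !.data$valid),
                      sides = "b", colour = "red") +
    ggplot2::facet_wrap(~axis, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "iris centre (px)")
  if (!is.null(truth)) {
    tl <- tidyr::pivot_longer(
      dplyr::select(tibble::as_tibble(truth), "frame_index", "x", "y"),
      c("x", "y"), names_to = "axis", values_to = "px")
    # align truth to the trajectory's time base via frame index
    m <- match(tl$frame_index, object$frame_index)
    tl <- tl[!is.na(m), ]
    tl$time_s <- object$time_s[m[!is.na(m)]]
    p <- p + ggplot2::geom_point(data = tl, shape = 1, colour = "blue",
                                 na.rm = TRUE)
  }
  p
}

#' Plot a grouped comparison table
#'
#' Bar chart of a chosen metric per axis and group, mirroring the layout of
#' grouped validation tables.
#'
#' @param comparison Output of [compare_groups()].
#' @param metric One of `"MAE"`, `"MPE"`, `"RMSE"`, `"PCC_r"`.
#' @param fill Name of the grouping column mapped to fill; default the
#'   first non-metric column.
#' @return A ggplot object.
#' @export
plot_comparison <- function(comparison, metric = "MAE", fill = NULL) {
  stopifnot(metric %in% c("MAE", "MPE", "RMSE", "PCC_r"))
  keys <- setdiff(names(comparison),
                  c("axis", "MAE", "MPE", "RMSE", "PCC_r", "PCC_p", "n",
                    "best_mae", "best_mpe", "best_rmse", "best_pcc"))
  if (is.null(fill)) fill <- keys[1]
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = .data$axis, y = .data[[metric]],
                               fill = .data[[fill]])) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "axis", y = metric)
}

#' Display a grayscale frame
#'
#' @param img Grayscale matrix on \[0, 255\].
#' @param centre Optional `(x, y)` marker (e.g. a detected iris centre).
#' @return A ggplot object (raster heatmap in image orientation: origin at
#'   the top-left, y growing downward).
#' @export
plot_eye_frame <- function(img, centre = NULL) {
  df <- expand.grid(y = 0:(nrow(img) - 1), x = 0:(ncol(img) - 1))
  df$value <- as.vector(img)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
  if (!is.null(centre))
    p <- p + ggplot2::annotate("point", x = centre[1], y = centre[2],
                               colour = "red", shape = 3, size = 3)
  p
}
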