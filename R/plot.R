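# ggplot2 visualisation helpers.

rgb_to_tibble <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  tibble(x = rep(0:(w - 1), each = h),
         y = rep(0:(h - 1), times = w),
         fill = grDevices::rgb(img[, , 1], img[, , 2], img[, , 3]))
}

snake_to_tibble <- function(pts, what) {
  p <- unclass(pts)
  tibble(x = c(p[, 1], p[1, 1]), y = c(p[, 2], p[1, 2]), contour = what)
}

#' Plot a thermogram image
#'
#' @param img H x W x 3 RGB array or a `phantom_sample`.
#' @return A ggplot object (y axis pointing down, pixel aspect ratio 1).
#' @export
plot_thermogram <- function(img) {
  if (inherits(img, "phantom_sample")) img <- img$image
  check_rgb(img)
  df <- rgb_to_tibble(img)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Overlay a segmentation on its thermogram
#'
#' Shows the image with the initial (contracted ellipse) and converged
#' snake contours of both breasts.
#'
#' @param object A `thermo_segmentation` from [segment_breasts()].
#' @param img The RGB image that was segmented (gray image used if
#'   omitted).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.thermo_segmentation <- function(object, img = NULL, ...) {
  base <- if (!is.null(img)) {
    plot_thermogram(img)
  } else {
    g <- object$gray
    plot_thermogram(array(rep(g, 3), c(dim(g), 3)))
  }
  cont <- dplyr::bind_rows(
    snake_to_tibble(object$initial$left, "initial"),
    snake_to_tibble(object$initial$right, "initial"),
    snake_to_tibble(object$snakes$left, "converged"),
    snake_to_tibble(object$snakes$right, "converged"))
  base +
    ggplot2::geom_path(
      data = cont,
      ggplot2::aes(.data$x, .data$y, colour = .data$contour,
                   group = interaction(.data$contour,
                                       rep(1:4, each = nrow(cont) / 4))),
      linewidth = 0.4) +
    ggplot2::scale_colour_manual(values = c(initial = "white",
                                            converged = "black"))
}

#' Plot the curvature function of a margin curve
#'
#' Curvature against arc length, with detected peaks highlighted - the
#' working view used to choose the delimiting salient points of each
#' breast.
#'
#' @param profile A `curvature_profile`.
#' @param peaks Optional integer peak indices (from
#'   [find_curvature_peaks()]).
#' @return A ggplot object.
#' @export
plot_curvature <- function(profile, peaks = integer()) {
  df <- tidy(profile)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$s, .data$k)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "arc length (px)", y = "curvature k (1/px)")
  if (length(peaks))
    p <- p + ggplot2::geom_point(data = df[peaks, ], colour = "red", size = 2)
  p
}

#' Bar chart of cross-validated quality indicators
#'
#' @param object A `thermo_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.thermo_cv <- function(object, ...) {
  m <- object$metrics
  df <- tibble(indicator = factor(names(m), levels = names(m)),
               value = as.numeric(m[1, ]))
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$indicator, .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("2-fold CV, %s", object$spec$kind))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
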