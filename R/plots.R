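#' Plot a meridional profile curve
#'
#' Mirrors the half-profile about the symmetry axis and draws it with
#' the apex on top and the substrate below, the orientation in which
#' side-view images are acquired.
#'
#' @param object A `profile_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.profile_curve <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(x = object$x, z = object$z),
    tibble(x = -rev(object$x), z = rev(object$z))
  )
  h <- max(object$z)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = h - .data$z)) +
    ggplot2::geom_path(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "radius", y = "height above substrate") +
    ggplot2::theme_minimal()
}

#' Plot a tension fit as predicted profile plus observed extents
#'
#' @param object A `tension_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tension_fit <- function(object, ...) {
  prof <- integrate_profile(object$params)
  p <- autoplot(prof)
  obs <- object$observed
  p +
    ggplot2::geom_hline(yintercept = c(0, obs$h), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_vline(xintercept = c(-obs$w / 2, obs$w / 2),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      title = if (is.finite(object$gamma_mn_per_m)) {
        sprintf("gamma = %.3g mN/m", object$gamma_mn_per_m)
      } else {
        sprintf("not measurably flattened (gamma >= %.3g mN/m)",
                object$gamma_lower_bound_mn_per_m)
      },
      subtitle = "fitted profile (solid), observed h and w (dashed)"
    )
}

#' Overlay an extracted contour and a fitted model profile
#'
#' Quality-control view of the inverse fit: the per-row contour
#' extracted from the image (points) with the fitted equilibrium
#' profile superimposed (red line), in pixel coordinates.
#'
#' @param extraction Result of [extract_geometry()].
#' @param fit A `tension_fit` for the same aggregate.
#' @param scale_um_per_px Pixel size used during extraction.
#' @return A ggplot object.
#' @export
plot_profile_overlay <- function(extraction, fit, scale_um_per_px) {
  prof <- integrate_profile(fit$params)
  axis <- extraction$axis_px
  sub <- extraction$substrate_row
  contour <- extraction$contour
  model <- dplyr::bind_rows(
    tibble(col = axis + prof$x / scale_um_per_px,
           row = sub - (max(prof$z) - prof$z) / scale_um_per_px),
    tibble(col = axis - rev(prof$x) / scale_um_per_px,
           row = sub - (max(prof$z) - rev(prof$z)) / scale_um_per_px)
  )
  edges <- dplyr::bind_rows(
    tibble(col = contour$left, row = contour$row),
    tibble(col = contour$right, row = contour$row)
  )
  ggplot2::ggplot() +
    ggplot2::geom_point(data = edges,
                        ggplot2::aes(x = .data$col, y = .data$row),
                        size = 0.3, colour = "grey30") +
    ggplot2::geom_path(data = model,
                       ggplot2::aes(x = .data$col, y = .data$row),
                       colour = "red", linewidth = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column (px)", y = "row (px)") +
    ggplot2::theme_minimal()
}

#' Notched boxplot of a value by condition
#'
#' The summary plot style used for group comparisons: notched boxes
#' (median, quartiles, McGill notches) with the raw points jittered on
#' top.
#'
#' @param data A tidy data frame.
#' @param value Name of the numeric column.
#' @param group Name of the condition column.
#' @return A ggplot object.
#' @export
plot_notched_box <- function(data, value, group = "condition") {
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[group]],
                                     y = .data[[value]])) +
    ggplot2::geom_boxplot(notch = TRUE, outlier.shape = NA,
                          fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL)
}

#' Plot the fitted surface tensions of a study report
#'
#' @param object A `study_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_report <- function(object, ...) {
  dat <- object$tension %>% filter(is.finite(.data$gamma_mn_per_m))
  plot_notched_box(dat, "gamma_mn_per_m") +
    ggplot2::labs(y = "surface tension (mN/m)")
}
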