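#' Plot a CSD volume as depth-plane heatmaps
#'
#' Tiles the tangential planes of a CSD volume (non-guard nodes), faceted
#' by depth. Sinks (negative CSD) are blue, sources red.
#'
#' @param object a [csd_volume()].
#' @param planes z-plane indices to show (default: four planes spanning
#'   the non-guard depth range).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.csd_volume <- function(object, planes = NULL, ...) {
  m <- grid_counts(object)
  gp <- attr(object, "guard_planes")
  if (is.null(planes)) {
    zr <- (gp[3] + 1L):(m[3] - gp[3])
    planes <- unique(round(seq(min(zr), max(zr), length.out = 4L)))
  }
  df <- dplyr::filter(tibble::as_tibble(object),
                      .data$iz %in% planes, !.data$guard)
  df$csd <- as.numeric(df$csd)
  df$depth_um <- factor(df$z)
  lim <- max(abs(df$csd))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$csd)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(ggplot2::vars(.data$depth_um),
                        labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B",
                                  limits = c(-lim, lim), name = "CSD") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)")
}

#' Plot the GCV curve of a fitted vCSD inverse
#'
#' Score as a function of the regularization weight (log-log), with the
#' selected lambda marked.
#'
#' @param object a [fit_vcsd()] result fitted with `lambda = "gcv"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.vcsd_fit <- function(object, ...) {
  if (is.null(object$gcv)) {
    stop("fit was produced with a fixed lambda; no GCV curve to plot",
         call. = FALSE)
  }
  ggplot2::ggplot(object$gcv, ggplot2::aes(x = .data$lambda,
                                           y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$lambda, linetype = 2,
                        color = "#B2182B") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(lambda), y = "GCV score")
}

#' Plot a noise-by-pitch sweep
#'
#' Median reconstruction error as a function of noise level, by electrode
#' pitch, faceted by method.
#'
#' @param results a [run_noise_resolution_sweep()] tibble.
#' @return A ggplot object.
#' @export
plot_noise_resolution <- function(results) {
  med <- dplyr::summarise(
    dplyr::group_by(results, .data$method, .data$beta, .data$pitch_um),
    re = stats::median(.data$re), .groups = "drop")
  ggplot2::ggplot(med, ggplot2::aes(x = .data$beta, y = .data$re,
                                    color = factor(.data$pitch_um))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$method)) +
    ggplot2::labs(x = expression(beta), y = "reconstruction error",
                  color = "pitch (um)")
}

#' Plot anatomical and functional barrels
#'
#' Overlays the functional barrel (fill) on the anatomical mask (outline
#' points) over the layer-4 plane.
#'
#' @param anatomical a [barrel_mask()].
#' @param functional a `functional_barrel` from [select_alpha()].
#' @return A ggplot object.
#' @export
plot_barrel_overlay <- function(anatomical, functional) {
  df <- tibble::tibble(
    x = anatomical$x, y = anatomical$y,
    functional = factor(functional$mask),
    anatomical = anatomical$mask == 1L
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$functional)) +
    ggplot2::geom_point(data = dplyr::filter(df, .data$anatomical),
                        shape = 21, size = 1.6, color = "cyan3") +
    ggplot2::scale_fill_manual(values = c(`0` = "grey95", `1` = "#FDD835")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", fill = "functional")
}
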