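#' Tidy and glance methods
#'
#' broom-style accessors: `tidy()` returns the per-observation tibble of a
#' result (ROC points, Bland-Altman pairs, per-image evaluation rows,
#' per-image calibration bests), `glance()` a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name cmhseg-tidiers
NULL

#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @rdname cmhseg-tidiers
#' @exportS3Method generics::tidy
tidy.cmh_roc <- function(x, ...) x$points

#' @rdname cmhseg-tidiers
#' @exportS3Method generics::glance
glance.cmh_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_points = nrow(x$points))
}

#' @rdname cmhseg-tidiers
#' @exportS3Method generics::tidy
tidy.cmh_bland_altman <- function(x, ...) x$pairs

#' @rdname cmhseg-tidiers
#' @exportS3Method generics::glance
glance.cmh_bland_altman <- function(x, ...) {
  tibble::tibble(mean_diff = x$mean_diff, loa_lower = x$loa[["lower"]],
                 loa_upper = x$loa[["upper"]], sd_diff = x$sd_diff,
                 n_pairs = nrow(x$pairs), percent = x$percent)
}

#' @rdname cmhseg-tidiers
#' @exportS3Method generics::glance
glance.cmh_icc <- function(x, ...) {
  tibble::tibble(icc = x$icc, ci_lower = x$ci[["lower"]],
                 ci_upper = x$ci[["upper"]], n_subjects = x$n, k_raters = x$k)
}

#' @rdname cmhseg-tidiers
#' @exportS3Method generics::tidy
tidy.cmh_evaluation <- function(x, ...) x$per_image

#' @rdname cmhseg-tidiers
#' @exportS3Method generics::glance
glance.cmh_evaluation <- function(x, ...) {
  tibble::tibble(
    method = x$method, parameter = x$parameter,
    sensitivity = x$sensitivity, specificity = x$specificity,
    mean_dice = mean(x$per_image$dice),
    icc = if (is.null(x$icc)) NA_real_ else x$icc$icc,
    icc_lower = if (is.null(x$icc)) NA_real_ else x$icc$ci[["lower"]],
    icc_upper = if (is.null(x$icc)) NA_real_ else x$icc$ci[["upper"]],
    ba_mean_diff_pct = if (is.null(x$bland_altman)) NA_real_ else
      x$bland_altman$mean_diff,
    ba_loa_lower_pct = if (is.null(x$bland_altman)) NA_real_ else
      x$bland_altman$loa[["lower"]],
    ba_loa_upper_pct = if (is.null(x$bland_altman)) NA_real_ else
      x$bland_altman$loa[["upper"]],
    n_images = nrow(x$per_image))
}

#' @rdname cmhseg-tidiers
#' @exportS3Method generics::tidy
tidy.cmh_threshold_selection <- function(x, ...) x$per_image

#' @rdname cmhseg-tidiers
#' @exportS3Method generics::tidy
tidy.cmh_radius_selection <- function(x, ...) x$per_image

#' Plot a ROC sweep
#'
#' Sensitivity against 1-specificity with the chance diagonal and the AUC
#' in the subtitle.
#'
#' @param object A `cmh_roc`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cmh_roc <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = "Pixel-pooled ROC",
                  subtitle = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a Bland-Altman agreement analysis
#'
#' Differences against pair means with the mean-difference line (solid) and
#' the 95% limits of agreement (dashed).
#'
#' @param object A `cmh_bland_altman`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cmh_bland_altman <- function(object, ...) {
  ylab <- if (object$percent) "Difference (% of pair mean)" else
    "Difference (um^2)"
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$mean,
                                             y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$mean_diff) +
    ggplot2::geom_hline(yintercept = object$loa, linetype = "dashed") +
    ggplot2::labs(x = "Mean area of pair (um^2)", y = ylab,
                  title = "Bland-Altman agreement") +
    ggplot2::theme_minimal()
}

#' Plot a phasor histogram
#'
#' Log-scaled bin occupancy over the (H, S) plane, with the bluest bin
#' marked if located.
#'
#' @param object A `cmh_phasor_histogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cmh_phasor_histogram <- function(object, ...) {
  nz <- which(object$counts > 0, arr.ind = TRUE)
  step <- 2 / object$bins
  df <- tibble::tibble(
    H = -1 + (nz[, 2] - 0.5) * step,
    S = 1 - (nz[, 1] - 0.5) * step,
    count = object$counts[nz])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$H, y = .data$S,
                                        fill = log10(.data$count))) +
    ggplot2::geom_tile(width = step, height = step) +
    ggplot2::scale_fill_viridis_c(name = "log10 count") +
    ggplot2::coord_equal(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "H", y = "S", title = "RGB spectral phasor space") +
    ggplot2::theme_minimal()
  if (!is.null(object$bluest_center)) {
    p <- p + ggplot2::annotate("point", x = object$bluest_center[1],
                               y = object$bluest_center[2],
                               shape = 1, size = 4, colour = "red")
  }
  p
}
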