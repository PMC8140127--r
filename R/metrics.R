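#' Pixel-wise confusion counts
#'
#' @param pred,truth [cmh_mask()] objects on the same grid.
#' @return A one-row tibble with integer columns `tp`, `fp`, `tn`, `fn`
#'   summing to the pixel count.
#' @export
confusion <- function(pred, truth) {
  stopifnot(inherits(pred, "cmh_mask"), inherits(truth, "cmh_mask"))
  check_same_grid(pred, truth)
  p <- mask_values(pred); t <- mask_values(truth)
  tibble::tibble(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t))
}

#' Sensitivity and specificity from confusion counts
#'
#' `sens = tp/(tp+fn)`, `spec = tn/(tn+fp)`. Errors on an undefined
#' denominator (no positive or no negative truth pixels).
#'
#' @param counts A data frame with columns `tp`, `fp`, `tn`, `fn`
#'   (rows are summed, so per-image tables pool naturally).
#' @return Named numeric vector `c(sensitivity=, specificity=)`.
#' @export
sensitivity_specificity <- function(counts) {
  tp <- sum(counts$tp); fp <- sum(counts$fp)
  tn <- sum(counts$tn); fn <- sum(counts$fn)
  if (tp + fn == 0) stop("sensitivity undefined: no positive truth pixels", call. = FALSE)
  if (tn + fp == 0) stop("specificity undefined: no negative truth pixels", call. = FALSE)
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Dice similarity coefficient
#'
#' `2|A intersect B| / (|A| + |B|)`; two empty masks are in perfect
#' agreement, so the empty/empty case is defined as 1.
#'
#' @inheritParams confusion
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(pred, truth) {
  stopifnot(inherits(pred, "cmh_mask"), inherits(truth, "cmh_mask"))
  check_same_grid(pred, truth)
  p <- mask_values(pred); t <- mask_values(truth)
  denom <- sum(p) + sum(t)
  if (denom == 0) return(1)
  2 * sum(p & t) / denom
}

#' Percent error of a segmented area against ground truth
#'
#' `(a_seg - a_gt)/a_gt * 100`; parameter-selection procedures minimise its
#' absolute value.
#'
#' @param a_seg,a_gt Areas in square micrometres; `a_gt` must be positive.
#' @return Signed percent error.
#' @export
percent_error <- function(a_seg, a_gt) {
  if (any(a_gt <= 0)) stop("ground-truth area must be positive", call. = FALSE)
  (a_seg - a_gt) / a_gt * 100
}

#' Pixel-pooled ROC sweep
#'
#' Sweeps a segmentation parameter over `grid`; at each value, segments
#' every image, applies the first two post-processing steps (small-region
#' and isolated-speckle removal only — not large-area removal, hole filling,
#' or the ROI check), pools the pixel confusion counts across the dataset,
#' and records (sensitivity, specificity). The area under the curve is the
#' trapezoid integral of sensitivity over 1-specificity with `(0,0)` and
#' `(1,1)` anchor points appended.
#'
#' Pooling across all pixels of all images (rather than averaging per-image
#' rates) matches reporting a single dataset-level sensitivity/specificity
#' pair; set `pool = FALSE` to average per-image rates instead.
#'
#' @param data Dataset tibble with list-columns `image` and `truth`.
#' @param segmenter `function(image, parameter) -> cmh_mask`.
#' @param grid Parameter grid to sweep.
#' @param chain_spec Settings whose first two steps are applied in-sweep;
#'   default `filter_chain_spec("ratiometric")`.
#' @param pool Pool pixel counts across images (default) or average
#'   per-image sensitivities/specificities.
#' @param partial_chain Apply the two in-sweep filter steps (default TRUE);
#'   FALSE sweeps the raw segmentations, whose nestedness makes the curve
#'   exactly monotone.
#' @return A `cmh_roc`: list with tibble `points`
#'   (`parameter`, `sensitivity`, `specificity`) and `auc`.
#' @export
roc_sweep <- function(data, segmenter, grid,
                      chain_spec = filter_chain_spec("ratiometric"),
                      pool = TRUE, partial_chain = TRUE) {
  if (length(grid) == 0) stop("parameter grid is empty", call. = FALSE)
  if (nrow(data) == 0) stop("dataset is empty", call. = FALSE)
  grid <- sort(grid)
  # image-outer iteration so segmenters that cache per-image state (ratio
  # maps, phasor fields) pay their setup once per image, not once per grid
  # value
  tabs <- purrr::map(seq_len(nrow(data)), function(i) {
    purrr::map(grid, function(p) {
      seg <- segmenter(data$image[[i]], p)
      if (partial_chain) {
        seg <- remove_small(seg, chain_spec$min_area_um2)
        seg <- remove_isolated_small(seg, chain_spec$isolated_max_area_um2,
                                     chain_spec$isolation_distance_um)
      }
      confusion(seg, data$truth[[i]])
    })
  })
  pts <- purrr::map(seq_along(grid), function(j) {
    per_image <- purrr::map(tabs, j)
    if (pool) {
      ss <- sensitivity_specificity(dplyr::bind_rows(per_image))
    } else {
      mat <- vapply(per_image, sensitivity_specificity, numeric(2))
      ss <- rowMeans(mat)
    }
    tibble::tibble(parameter = grid[j], sensitivity = ss[["sensitivity"]],
                   specificity = ss[["specificity"]])
  })
  points <- dplyr::bind_rows(pts)
  structure(list(points = points, auc = roc_auc(points)),
            class = "cmh_roc")
}

# trapezoid AUC over (1-spec, sens) with (0,0) and (1,1) anchors
roc_auc <- function(points) {
  fpr <- c(0, 1 - points$specificity, 1)
  tpr <- c(0, points$sensitivity, 1)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' @export
print.cmh_roc <- function(x, ...) {
  cat(sprintf("<ROC sweep> %d parameter values, AUC %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' Intraclass correlation coefficient, two-way random effects, absolute
#' agreement, single measure
#'
#' ICC(A,1) in the McGraw & Wong taxonomy (equivalently ICC(2,1)): both
#' subjects and raters are random effects and systematic rater offsets count
#' against agreement. Computed from the two-way ANOVA mean squares
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with `n` subjects and `k` raters; the 95% confidence interval uses the
#' F-distribution method of McGraw & Wong.
#'
#' @param x Numeric matrix or data frame, `n` subjects (rows) by `k` raters
#'   (columns); no missing cells; `n >= 5`, `k >= 2`.
#' @param conf_level Confidence level, default 0.95.
#' @return A list: `icc`, `ci` (length-2 lower/upper), `n`, `k`, and the
#'   mean squares `msr`, `msc`, `mse`.
#' @export
icc_absolute_agreement <- function(x, conf_level = 0.95) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing cells are not supported", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 5 || k < 2) stop("need at least 5 subjects and 2 raters", call. = FALSE)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)           # subjects
  ssc <- n * sum((col_m - grand)^2)           # raters
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)  # residual
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom <= 0 || (msr == 0 && msc == 0 && mse == 0)) {
    stop("ICC undefined: degenerate variance structure", call. = FALSE)
  }
  r <- (msr - mse) / denom
  alpha <- 1 - conf_level
  a <- (k * r) / (n * (1 - r))
  b <- 1 + (k * r * (n - 1)) / (n * (1 - r))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  structure(list(icc = r, ci = c(lower = lower, upper = upper), n = n, k = k,
                 msr = msr, msc = msc, mse = mse, conf_level = conf_level),
            class = "cmh_icc")
}

#' @export
print.cmh_icc <- function(x, ...) {
  cat(sprintf("<ICC(A,1)> %.4f (%.0f%% CI %.4f-%.4f), n = %d subjects, k = %d raters\n",
              x$icc, 100 * x$conf_level, x$ci[1], x$ci[2], x$n, x$k))
  invisible(x)
}

#' Bland-Altman agreement on paired areas
#'
#' For each pair, the difference is `(a - b)` expressed as a percentage of
#' the pair mean when `percent = TRUE` (the standard percent Bland-Altman,
#' matching plots whose x-axis is the pair mean), or the raw difference
#' otherwise. Summaries are the mean difference and the 95% limits of
#' agreement `mean +/- 1.96 * SD`. Pairs whose mean is zero have no percent
#' difference and are excluded with a warning.
#'
#' @param a,b Paired area vectors (square micrometres), equal length.
#' @param percent Express differences as percent of the pair mean (default).
#' @return A `cmh_bland_altman`: list with `mean_diff`, `loa`
#'   (lower/upper), `sd_diff`, and tibble `pairs`
#'   (`mean`, `difference`).
#' @export
bland_altman <- function(a, b, percent = TRUE) {
  if (length(a) != length(b)) stop("`a` and `b` must be paired", call. = FALSE)
  m <- (a + b) / 2
  if (percent) {
    bad <- m == 0
    if (any(bad)) {
      warning(sum(bad), " pair(s) with zero mean excluded from percent differences",
              call. = FALSE)
      a <- a[!bad]; b <- b[!bad]; m <- m[!bad]
    }
    d <- (a - b) / m * 100
  } else {
    d <- a - b
  }
  if (length(d) == 0) stop("no usable pairs", call. = FALSE)
  md <- mean(d)
  sd_d <- stats::sd(d)
  if (is.na(sd_d)) sd_d <- 0  # single pair
  structure(list(mean_diff = md,
                 loa = c(lower = md - 1.96 * sd_d, upper = md + 1.96 * sd_d),
                 sd_diff = sd_d,
                 percent = percent,
                 pairs = tibble::tibble(mean = m, difference = d)),
            class = "cmh_bland_altman")
}

#' @export
print.cmh_bland_altman <- function(x, ...) {
  unit <- if (x$percent) "%" else " um^2"
  cat(sprintf("<Bland-Altman> mean difference %.3g%s, 95%% LoA [%.3g, %.3g]%s (n = %d)\n",
              x$mean_diff, unit, x$loa[1], x$loa[2], unit, nrow(x$pairs)))
  invisible(x)
}
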