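#' Per-pixel segmentation ratio
#'
#' Computes the ratiometric statistic that discriminates Prussian blue-stained
#' pixels from the Nuclear Fast Red background:
#' \deqn{\mathrm{ratio} = I_{red} I_{green} / I_{blue}^2}
#' Blue-dominant pixels (high blue, low red/green) score well below 1, the
#' pink counterstain scores above 1, and achromatic pixels score exactly 1.
#' The statistic is invariant to uniform intensity scaling, so no white
#' balance or bit-depth normalisation is applied.
#'
#' Pixels with zero blue intensity are assigned a large finite sentinel
#' (`1e12`) rather than `Inf`/`NaN`: a zero-blue pixel carries no Prussian
#' blue signal and must never fall below any realistic threshold, including
#' pure-black pixels where the numerator is also zero.
#'
#' @param image A [cmh_image()].
#' @return A `cmh_ratio_map`: an `H x W` numeric matrix of ratio values with
#'   the image's calibration attached.
#' @export
compute_ratio <- function(image) {
  stopifnot(inherits(image, "cmh_image"))
  px <- unclass(image)
  r <- channel(px, 1); g <- channel(px, 2); b <- channel(px, 3)
  vals <- ifelse(b > 0, r * g / b^2, RATIO_SENTINEL)
  structure(vals,
            pixel_size_um = pixel_size(image),
            source_id = source_id(image),
            class = "cmh_ratio_map")
}

# sentinel for zero-blue pixels; exceeds any plausible threshold grid
RATIO_SENTINEL <- 1e12

#' Threshold a ratio map into a candidate mask
#'
#' Pixels whose segmentation ratio is strictly below `threshold` are included
#' in the candidate mask. Masks are nested in the threshold: a smaller
#' threshold always yields a subset.
#'
#' @param ratio_map A `cmh_ratio_map` from [compute_ratio()].
#' @param threshold Positive cutoff on the ratio.
#' @return A [cmh_mask()].
#' @export
segment_by_ratio <- function(ratio_map, threshold) {
  stopifnot(inherits(ratio_map, "cmh_ratio_map"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("`threshold` must be a single positive number", call. = FALSE)
  }
  vals <- unclass(ratio_map)
  attributes(vals) <- list(dim = dim(vals))
  cmh_mask(vals < threshold, pixel_size(ratio_map),
           source_id = source_id(ratio_map))
}

#' Default threshold grid
#'
#' Geometric grid of `n` thresholds spanning `lo` to `hi`; the default spans
#' `[0.05, 5]` with 101 points, bracketing the achromatic value 1 from both
#' sides.
#'
#' @param lo,hi Grid endpoints (positive).
#' @param n Number of grid points.
#' @return Numeric vector of thresholds.
#' @export
ratio_threshold_grid <- function(lo = 0.05, hi = 5, n = 101) {
  stopifnot(lo > 0, hi > lo, n >= 2)
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Select the optimal segmentation-ratio threshold on a dataset
#'
#' For each image, sweeps the threshold grid, applies the full
#' post-processing chain to every candidate segmentation, and finds the
#' threshold minimising the absolute percent error between segmented and
#' ground-truth area. The dataset-level optimum is the *median* of the
#' per-image best thresholds (midpoint of the central pair for even counts).
#' Ties within an image resolve to the smallest qualifying threshold
#' (conservative segmentation). Images with zero ground-truth area cannot
#' define a percent error and are excluded with a warning.
#'
#' @param data A dataset tibble with list-columns `image` ([cmh_image()]) and
#'   `truth` ([cmh_mask()]), e.g. from [generate_dataset()]. Ground-truth
#'   masks should already be post-processed consensus masks.
#' @param grid Threshold grid; default [ratio_threshold_grid()].
#' @param chain_spec Post-processing settings applied to each candidate
#'   segmentation before the area comparison; default
#'   `filter_chain_spec("ratiometric")`.
#' @param rois Optional list of coarse-ROI masks (one per image) applied as
#'   the final chain step.
#' @return A `cmh_threshold_selection`: list with `optimal_threshold`,
#'   tibble `per_image` (`image_id`, `best_threshold`, `percent_error`), and
#'   the `grid`.
#' @export
select_optimal_threshold <- function(data,
                                     grid = ratio_threshold_grid(),
                                     chain_spec = filter_chain_spec("ratiometric"),
                                     rois = NULL) {
  sel <- select_optimal_parameter(
    data, grid, chain_spec, rois,
    segment_fun = ratio_segmenter(),
    combine = stats::median
  )
  structure(list(optimal_threshold = sel$optimal,
                 per_image = sel$per_image,
                 grid = grid),
            class = "cmh_threshold_selection")
}

# Shared sweep: per image, pick the grid value minimising |percent error|
# of post-processed area vs truth area; combine per-image bests.
select_optimal_parameter <- function(data, grid, chain_spec, rois,
                                     segment_fun, combine) {
  if (length(grid) == 0) stop("parameter grid is empty", call. = FALSE)
  if (nrow(data) == 0) stop("dataset is empty", call. = FALSE)
  grid <- sort(grid)
  rows <- purrr::map(seq_len(nrow(data)), function(i) {
    image <- data$image[[i]]
    truth <- data$truth[[i]]
    a_gt <- mask_area_um2(truth)
    if (a_gt == 0) {
      warning("excluding image '", source_id(image),
              "' with zero ground-truth area", call. = FALSE)
      return(NULL)
    }
    roi <- if (is.null(rois)) NULL else rois[[i]]
    errs <- purrr::map_dbl(grid, function(p) {
      seg <- run_chain(segment_fun(image, p), chain_spec, roi = roi)
      abs(percent_error(mask_area_um2(seg), a_gt))
    })
    j <- which.min(errs)  # which.min takes the first, i.e. smallest grid value
    tibble::tibble(image_id = source_id(image),
                   best = grid[j],
                   percent_error = errs[j])
  })
  per_image <- dplyr::bind_rows(rows)
  if (nrow(per_image) == 0) {
    stop("no image with positive ground-truth area", call. = FALSE)
  }
  list(optimal = combine(per_image$best), per_image = per_image)
}

#' @export
print.cmh_threshold_selection <- function(x, ...) {
  cat(sprintf("<threshold selection> optimal ratio threshold %.4g (median of %d per-image bests)\n",
              x$optimal_threshold, nrow(x$per_image)))
  invisible(x)
}
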