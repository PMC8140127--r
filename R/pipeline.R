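#' Segment one image with a named method
#'
#' Dispatches to the ratiometric threshold rule or the phasor gate at the
#' given parameter value (threshold or radius respectively), without
#' post-processing.
#'
#' @param image A [cmh_image()].
#' @param method `"ratiometric"` or `"phasor"`.
#' @param parameter Ratio threshold or gate radius.
#' @param bins Phasor histogram bins per axis (phasor method only).
#' @return A [cmh_mask()].
#' @export
segment_image <- function(image, method = c("ratiometric", "phasor"),
                          parameter, bins = 256) {
  method <- match.arg(method)
  switch(method,
         ratiometric = segment_by_ratio(compute_ratio(image), parameter),
         phasor = phasor_segment_image(image, parameter, bins = bins))
}

#' Memoising segmenters for parameter sweeps
#'
#' Return a `function(image, parameter) -> cmh_mask` that caches the
#' per-image precomputation (the ratio map, or the phasor field plus the
#' bluest-bin gate centre) for the most recent image, so sweeping many
#' parameter values over the same image only pays the transform once.
#' Suitable as the `segmenter` argument of [roc_sweep()].
#'
#' @param bins Phasor histogram bins per axis.
#' @return A segmenter closure.
#' @export
ratio_segmenter <- function() {
  last_id <- NULL; rmap <- NULL
  function(image, threshold) {
    if (!identical(source_id(image), last_id)) {
      rmap <<- compute_ratio(image)
      last_id <<- source_id(image)
    }
    segment_by_ratio(rmap, threshold)
  }
}

#' @rdname ratio_segmenter
#' @export
phasor_segmenter <- function(bins = 256) {
  last_id <- NULL; field <- NULL; center <- NULL
  function(image, radius) {
    if (!identical(source_id(image), last_id)) {
      field <<- compute_phasor(image, normalize = TRUE)
      h <- find_bluest_bin(build_phasor_histogram(field, bins = bins))
      center <<- h$bluest_center
      last_id <<- source_id(image)
    }
    segment_by_phasor(field, phasor_gate(center, radius))
  }
}

#' Evaluate a segmentation method on a dataset
#'
#' Runs the method at a fixed parameter on every image, applies the full
#' post-processing chain, and summarises agreement with the ground truth:
#' per-image areas, percent errors and Dice; dataset-pooled sensitivity and
#' specificity; the two-way random-effects absolute-agreement ICC between
#' segmented and truth areas (when at least five images are available); and
#' percent Bland-Altman limits of agreement.
#'
#' @param data Dataset tibble with list-columns `image` and `truth`.
#' @param method `"ratiometric"` or `"phasor"`.
#' @param parameter Threshold or radius, usually from
#'   [select_optimal_threshold()] / [select_optimal_radius()].
#' @param chain_spec Post-processing settings; defaults to the method's
#'   standard chain.
#' @param rois Optional per-image coarse-ROI masks.
#' @param bins Phasor histogram resolution.
#' @return A `cmh_evaluation`: list with tibble `per_image`, `sensitivity`,
#'   `specificity`, `icc` (a `cmh_icc` or NULL), `bland_altman`
#'   (a `cmh_bland_altman` or NULL), `method`, `parameter`.
#' @export
evaluate_segmentation <- function(data, method = c("ratiometric", "phasor"),
                                  parameter,
                                  chain_spec = NULL, rois = NULL, bins = 256) {
  method <- match.arg(method)
  if (is.null(chain_spec)) chain_spec <- filter_chain_spec(method)
  if (nrow(data) == 0) stop("dataset is empty", call. = FALSE)
  rows <- purrr::map(seq_len(nrow(data)), function(i) {
    image <- data$image[[i]]
    truth <- data$truth[[i]]
    roi <- if (is.null(rois)) NULL else rois[[i]]
    seg <- run_chain(segment_image(image, method, parameter, bins = bins),
                     chain_spec, roi = roi)
    cc <- confusion(seg, truth)
    a_gt <- mask_area_um2(truth)
    dplyr::bind_cols(
      tibble::tibble(image_id = source_id(image), method = method,
                     parameter = parameter,
                     segmented_area_um2 = mask_area_um2(seg),
                     truth_area_um2 = a_gt,
                     percent_error = if (a_gt > 0)
                       percent_error(mask_area_um2(seg), a_gt) else NA_real_,
                     dice = dice(seg, truth)),
      cc)
  })
  per_image <- dplyr::bind_rows(rows)
  ss <- sensitivity_specificity(per_image)
  icc <- NULL
  if (nrow(per_image) >= 5) {
    icc <- tryCatch(
      icc_absolute_agreement(cbind(per_image$segmented_area_um2,
                                   per_image$truth_area_um2)),
      error = function(e) NULL)
  }
  ba <- tryCatch(
    suppressWarnings(bland_altman(per_image$segmented_area_um2,
                                  per_image$truth_area_um2, percent = TRUE)),
    error = function(e) NULL)
  structure(list(per_image = per_image,
                 sensitivity = ss[["sensitivity"]],
                 specificity = ss[["specificity"]],
                 icc = icc, bland_altman = ba,
                 method = method, parameter = parameter),
            class = "cmh_evaluation")
}

#' @export
print.cmh_evaluation <- function(x, ...) {
  cat(sprintf("<evaluation> %s @ %.4g on %d images\n", x$method, x$parameter,
              nrow(x$per_image)))
  cat(sprintf("  sensitivity %.3f, specificity %.3f, mean Dice %.3f\n",
              x$sensitivity, x$specificity, mean(x$per_image$dice)))
  if (!is.null(x$icc)) {
    cat(sprintf("  area ICC(A,1) %.3f (95%% CI %.3f-%.3f)\n",
                x$icc$icc, x$icc$ci[1], x$icc$ci[2]))
  }
  if (!is.null(x$bland_altman)) {
    cat(sprintf("  Bland-Altman mean difference %.1f%%, LoA [%.1f, %.1f]%%\n",
                x$bland_altman$mean_diff, x$bland_altman$loa[1],
                x$bland_altman$loa[2]))
  }
  invisible(x)
}

#' Consensus ground truth for a whole dataset
#'
#' Majority-votes each image's annotations and applies the ground-truth
#' post-processing chain (the removal steps only). Returns the dataset with
#' its `truth` column replaced by the processed consensus, ready for
#' calibration and evaluation.
#'
#' @param data Dataset tibble with an `annotations` list-column.
#' @param min_votes Votes required for a consensus-positive pixel.
#' @param chain_spec Ground-truth chain settings.
#' @return The dataset tibble with consensus `truth`.
#' @export
consensus_truth <- function(data, min_votes = 2,
                            chain_spec = filter_chain_spec("truth")) {
  data$truth <- purrr::map(data$annotations, function(anns) {
    run_chain(majority_vote(anns, min_votes = min_votes), chain_spec)
  })
  data
}
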