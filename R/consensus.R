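#' Majority-vote consensus mask
#'
#' Builds the ground-truth mask from several annotators: a pixel is
#' consensus-positive iff at least `min_votes` annotators marked it. With the
#' default `min_votes = 2` and four annotators this is the "at least two of
#' four" majority rule. `min_votes = 1` gives the union of the masks,
#' `min_votes = K` their intersection.
#'
#' @param annotations List of [cmh_mask()] objects on a common grid and
#'   calibration (an annotation set).
#' @param min_votes Minimum number of positive votes, `1 <= min_votes <= K`.
#' @return A [cmh_mask()].
#' @export
majority_vote <- function(annotations, min_votes = 2) {
  k <- length(annotations)
  if (k < 1) stop("need at least one annotation mask", call. = FALSE)
  if (min_votes < 1 || min_votes > k) {
    stop("`min_votes` must be between 1 and the number of annotators (", k, ")",
         call. = FALSE)
  }
  ref <- annotations[[1]]
  votes <- matrix(0L, nrow(ref), ncol(ref))
  for (m in annotations) {
    stopifnot(inherits(m, "cmh_mask"))
    check_same_grid(ref, m)
    votes <- votes + mask_values(m)
  }
  cmh_mask(votes >= min_votes, pixel_size(ref), source_id = "consensus")
}

#' Per-annotator segmented areas
#'
#' Total segmented area per annotator in square micrometres, one row per
#' image; feeding a stack of these rows into [icc_absolute_agreement()]
#' quantifies inter-annotator agreement.
#'
#' @inheritParams majority_vote
#' @param image_id Identifier for the table row.
#' @return A one-row tibble: `image_id`, then `annotator_1 ... annotator_K`
#'   areas in square micrometres.
#' @export
annotator_areas <- function(annotations, image_id = "image") {
  areas <- vapply(annotations, mask_area_um2, numeric(1))
  out <- tibble::as_tibble(as.list(stats::setNames(
    areas, paste0("annotator_", seq_along(areas)))))
  dplyr::bind_cols(tibble::tibble(image_id = image_id), out)
}
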