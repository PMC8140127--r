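#' Label connected foreground regions
#'
#' Connected-component labelling of a binary mask. Foreground uses
#' 8-connectivity by default (diagonal contact joins regions); 4-connectivity
#' is available. Region areas are physical: pixel count times the squared
#' pixel size.
#'
#' @param mask A [cmh_mask()].
#' @param connectivity 8 (default) or 4.
#' @return A `cmh_regions`: list with `labels` (`H x W` integer matrix, 0 =
#'   background, labels contiguous from 1), a tibble `regions`
#'   (`label`, `n_px`, `area_um2`), and the calibration.
#' @export
label_regions <- function(mask, connectivity = 8) {
  stopifnot(inherits(mask, "cmh_mask"))
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8", call. = FALSE)
  m <- mask_values(mask)
  lab <- label_matrix(m, connectivity)
  k <- max(lab)
  counts <- if (k > 0) tabulate(lab[lab > 0L], nbins = k) else integer(0)
  structure(list(
    labels = lab,
    regions = tibble::tibble(label = seq_len(k), n_px = counts,
                             area_um2 = counts * pixel_size(mask)^2),
    pixel_size_um = pixel_size(mask),
    source_id = source_id(mask)),
    class = "cmh_regions")
}

# EBImage::bwlabel is 4-connected; for 8-connectivity, merge 4-labels that
# touch diagonally using a union-find over label ids.
label_matrix <- function(m, connectivity) {
  lab <- matrix(as.integer(round(EBImage::bwlabel(m * 1))), nrow(m), ncol(m))
  if (connectivity == 4 || max(lab) <= 1L) return(compact_labels(lab))
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # (i,j) vs (i+1,j+1)
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]   # (i,j+1) vs (i+1,j)
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    parent <- seq_len(max(lab))
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    roots <- vapply(seq_along(parent), find, integer(1))
    lab[lab > 0L] <- roots[lab[lab > 0L]]
  }
  compact_labels(lab)
}

# renumber labels to 1..K in order of first appearance (column-major)
compact_labels <- function(lab) {
  u <- unique(lab[lab > 0L])
  if (length(u)) {
    map <- integer(max(u))
    map[u] <- seq_along(u)
    lab[lab > 0L] <- map[lab[lab > 0L]]
  }
  lab
}

regions_to_mask <- function(regions, keep) {
  m <- matrix(regions$labels %in% keep, nrow(regions$labels), ncol(regions$labels))
  cmh_mask(m, regions$pixel_size_um, source_id = regions$source_id)
}

#' Filter-chain settings
#'
#' Bundles the post-processing thresholds with a method tag that decides
#' which steps apply. Defaults: regions below 5 um^2 removed; regions below
#' 50 um^2 that sit more than 50 um from every other region removed; regions
#' above 6000 um^2 removed (ratiometric and phasor only); interior holes
#' below 1.73 um^2 filled (phasor only). All inequalities are strict.
#'
#' @param method One of `"ratiometric"`, `"phasor"`, `"truth"`,
#'   `"deep_learning"`; selects which chain steps run.
#' @param min_area_um2 Small-region removal cutoff.
#' @param isolated_max_area_um2,isolation_distance_um Isolated-speckle rule.
#' @param max_area_um2 Large-region removal cutoff.
#' @param hole_fill_max_um2 Hole-filling cutoff.
#' @return A `cmh_chain_spec`.
#' @export
filter_chain_spec <- function(method = c("ratiometric", "phasor", "truth",
                                         "deep_learning"),
                              min_area_um2 = 5,
                              isolated_max_area_um2 = 50,
                              isolation_distance_um = 50,
                              max_area_um2 = 6000,
                              hole_fill_max_um2 = 1.73) {
  method <- match.arg(method)
  vals <- c(min_area_um2, isolated_max_area_um2, isolation_distance_um,
            max_area_um2, hole_fill_max_um2)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all filter thresholds must be positive", call. = FALSE)
  }
  structure(list(method = method,
                 min_area_um2 = min_area_um2,
                 isolated_max_area_um2 = isolated_max_area_um2,
                 isolation_distance_um = isolation_distance_um,
                 max_area_um2 = max_area_um2,
                 hole_fill_max_um2 = hole_fill_max_um2),
            class = "cmh_chain_spec")
}

#' Remove regions below an area cutoff
#'
#' Deletes connected regions whose physical area is strictly below
#' `min_area_um2`; a region at exactly the cutoff is kept.
#'
#' @param mask A [cmh_mask()] (labelled internally with 8-connectivity).
#' @param min_area_um2 Cutoff in square micrometres.
#' @return A [cmh_mask()], a pixel-wise subset of the input.
#' @export
remove_small <- function(mask, min_area_um2 = 5) {
  regions <- label_regions(mask)
  keep <- regions$regions$label[regions$regions$area_um2 >= min_area_um2]
  regions_to_mask(regions, keep)
}

#' Remove small isolated regions
#'
#' A region is removed iff its area is strictly below
#' `max_area_um2` *and* its minimum boundary-to-boundary Euclidean distance
#' (between pixel centres, in micrometres) to every other region strictly
#' exceeds `min_distance_um`. The rule targets scattered speckle far from any
#' real deposit; a mask containing a single region keeps it, since there is
#' no "closest spot" to measure against.
#'
#' @inheritParams remove_small
#' @param max_area_um2 Area clause cutoff.
#' @param min_distance_um Isolation distance in micrometres.
#' @return A [cmh_mask()], a pixel-wise subset of the input.
#' @export
remove_isolated_small <- function(mask, max_area_um2 = 50,
                                  min_distance_um = 50) {
  regions <- label_regions(mask)
  k <- nrow(regions$regions)
  if (k <= 1) return(regions_to_mask(regions, regions$regions$label))
  small <- regions$regions$label[regions$regions$area_um2 < max_area_um2]
  if (length(small) == 0) return(regions_to_mask(regions, regions$regions$label))
  bounds <- boundary_coords(regions)
  boxes <- t(vapply(bounds, function(b) {
    c(min(b[, 1]), max(b[, 1]), min(b[, 2]), max(b[, 2]))
  }, numeric(4)))
  dist_px <- min_distance_um / regions$pixel_size_um
  drop <- vapply(small, function(lb) {
    others <- setdiff(seq_len(k), lb)
    # bounding-box gap is a lower bound on the pixel distance: prune with it
    gaps <- pmax(boxes[others, 1] - boxes[lb, 2], boxes[lb, 1] - boxes[others, 2], 0)^2 +
            pmax(boxes[others, 3] - boxes[lb, 4], boxes[lb, 3] - boxes[others, 4], 0)^2
    for (ot in others[order(gaps)]) {
      gap2 <- max(boxes[ot, 1] - boxes[lb, 2], boxes[lb, 1] - boxes[ot, 2], 0)^2 +
              max(boxes[ot, 3] - boxes[lb, 4], boxes[lb, 3] - boxes[ot, 4], 0)^2
      if (gap2 > dist_px^2) break
      if (min_pair_dist2(bounds[[lb]], bounds[[ot]]) <= dist_px^2) return(FALSE)
    }
    TRUE
  }, logical(1))
  keep <- setdiff(regions$regions$label, small[drop])
  regions_to_mask(regions, keep)
}

# boundary pixel coordinates (row, col) per region: foreground pixels with a
# 4-neighbour outside the region's mask or on the image border
boundary_coords <- function(regions) {
  lab <- regions$labels
  fg <- lab > 0L
  h <- nrow(fg); w <- ncol(fg)
  interior <- matrix(FALSE, h, w)
  if (h > 2 && w > 2) {
    interior[2:(h - 1), 2:(w - 1)] <-
      fg[1:(h - 2), 2:(w - 1)] & fg[3:h, 2:(w - 1)] &
      fg[2:(h - 1), 1:(w - 2)] & fg[2:(h - 1), 3:w]
  }
  onb <- fg & !interior
  idx <- which(onb, arr.ind = TRUE)
  b <- split.data.frame(idx, lab[onb])
  b[order(as.integer(names(b)))]  # label order, not lexicographic
}

min_pair_dist2 <- function(a, b) {
  # pairwise squared distances between two boundary point sets (px units)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  min(d2)
}

#' Remove regions above an area cutoff
#'
#' Deletes connected regions whose physical area strictly exceeds
#' `max_area_um2`; a region at exactly the cutoff is kept. In the standard
#' chain this step applies only to the ratiometric and phasor methods, not
#' to the consensus ground truth.
#'
#' @inheritParams remove_small
#' @param max_area_um2 Cutoff in square micrometres.
#' @return A [cmh_mask()], a pixel-wise subset of the input.
#' @export
remove_large <- function(mask, max_area_um2 = 6000) {
  regions <- label_regions(mask)
  keep <- regions$regions$label[regions$regions$area_um2 <= max_area_um2]
  regions_to_mask(regions, keep)
}

#' Fill small interior holes
#'
#' Background components (4-connectivity) that do not touch the image border
#' and whose area is strictly below `max_hole_um2` are set to foreground.
#' Border-touching background is exterior by definition and never filled.
#' In the standard chain this step applies only to the phasor method.
#'
#' @inheritParams remove_small
#' @param max_hole_um2 Hole-area cutoff in square micrometres.
#' @return A [cmh_mask()]; only strictly interior pixels may be added.
#' @export
fill_small_holes <- function(mask, max_hole_um2 = 1.73) {
  m <- mask_values(mask)
  bg <- label_matrix(!m, connectivity = 4)
  k <- max(bg)
  if (k == 0) return(mask)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  counts <- tabulate(bg[bg > 0L], nbins = k)
  fill <- setdiff(which(counts * pixel_size(mask)^2 < max_hole_um2), border)
  if (length(fill)) m[bg %in% fill] <- TRUE
  cmh_mask(m, pixel_size(mask), source_id = source_id(mask))
}

#' Coarse-ROI manual check
#'
#' Intersects a segmentation with a user-drawn coarse region of interest,
#' discarding detections outside it (e.g. stain debris far from any
#' microhemorrhage). An all-true ROI is the identity.
#'
#' @inheritParams remove_small
#' @param roi A [cmh_mask()] on the same grid.
#' @return A [cmh_mask()].
#' @export
apply_roi_check <- function(mask, roi) {
  stopifnot(inherits(roi, "cmh_mask"))
  check_same_grid(mask, roi)
  cmh_mask(mask_values(mask) & mask_values(roi), pixel_size(mask),
           source_id = source_id(mask))
}

#' Run the ordered post-processing chain
#'
#' Applies, in order: small-region removal, isolated-speckle removal,
#' large-region removal (ratiometric/phasor methods only), small-hole
#' filling (phasor only), and the coarse-ROI check (if an ROI is given;
#' skipped for the deep-learning tag, whose high specificity makes it
#' unnecessary).
#'
#' @inheritParams remove_small
#' @param spec A [filter_chain_spec()].
#' @param roi Optional [cmh_mask()] for the final manual-check step.
#' @return A post-processed [cmh_mask()].
#' @export
run_chain <- function(mask, spec = filter_chain_spec("ratiometric"), roi = NULL) {
  stopifnot(inherits(spec, "cmh_chain_spec"))
  out <- remove_small(mask, spec$min_area_um2)
  out <- remove_isolated_small(out, spec$isolated_max_area_um2,
                               spec$isolation_distance_um)
  if (spec$method %in% c("ratiometric", "phasor")) {
    out <- remove_large(out, spec$max_area_um2)
  }
  if (spec$method == "phasor") {
    out <- fill_small_holes(out, spec$hole_fill_max_um2)
  }
  if (!is.null(roi) && spec$method != "deep_learning") {
    out <- apply_roi_check(out, roi)
  }
  out
}
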