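#' RGB spectral-phasor transform
#'
#' Projects each pixel's channel intensities onto the first Fourier harmonic
#' across the three channels, giving a 2-D phasor coordinate per pixel:
#' \deqn{H = \sum_{l=1}^{3} I_l \cos(2\pi l/3), \qquad
#'       S = \sum_{l=1}^{3} I_l \sin(2\pi l/3)}
#' with \eqn{l = 1} red, \eqn{2} green, \eqn{3} blue, i.e. cosine weights
#' \eqn{(-1/2, -1/2, 1)} and sine weights \eqn{(\sqrt3/2, -\sqrt3/2, 0)}.
#' Pure red, green, and blue therefore map to the vertices of an equilateral
#' triangle on the unit circle, and achromatic pixels map to the origin.
#'
#' By default each pixel's intensities are first divided by their sum, making
#' the coordinate a pure chromaticity in `[-1, 1]` that is invariant to
#' intensity scale; this is what makes a fixed-radius circular gate
#' meaningful. `normalize = FALSE` applies the literal unnormalised sums,
#' which scale linearly with intensity. Zero-intensity pixels map to (0, 0)
#' under normalisation.
#'
#' @param image A [cmh_image()].
#' @param normalize Divide each pixel by its channel sum first (default TRUE).
#' @return A `cmh_phasor_field`: list of matrices `H` and `S` plus the
#'   calibration, with a `normalized` flag.
#' @export
compute_phasor <- function(image, normalize = TRUE) {
  stopifnot(inherits(image, "cmh_image"))
  px <- unclass(image)
  r <- channel(px, 1); g <- channel(px, 2); b <- channel(px, 3)
  if (normalize) {
    tot <- r + g + b
    safe <- ifelse(tot > 0, tot, 1)  # zero-sum pixels -> (0,0)
    r <- r / safe; g <- g / safe; b <- b / safe
  }
  # cos(2pi/3) = cos(4pi/3) = -1/2, cos(2pi) = 1
  # sin(2pi/3) = +sqrt(3)/2, sin(4pi/3) = -sqrt(3)/2, sin(2pi) = 0
  H <- -0.5 * r - 0.5 * g + b
  S <- (sqrt(3) / 2) * (r - g)
  structure(list(H = H, S = S, normalized = normalize,
                 pixel_size_um = pixel_size(image),
                 source_id = source_id(image)),
            class = "cmh_phasor_field")
}

#' 2-D phasor histogram
#'
#' Bins the per-pixel (H, S) coordinates on a fixed grid over
#' `[-1, 1] x [-1, 1]`. Orientation follows display-matrix convention:
#' row index `x` runs from S = +1 (row 1) down to S = -1, column index `y`
#' from H = -1 (column 1) up to H = +1. Under this orientation the
#' "bluest" criterion of [find_bluest_bin()] — minimising `x/y` — favours
#' large-H bins (blue chromaticity) over the red counterstain's S > 0 bins.
#'
#' @param field A `cmh_phasor_field` (must be normalised so the axis range
#'   is fixed).
#' @param bins Number of bins per axis (square grid), default 256.
#' @return A `cmh_phasor_histogram`: list with `counts` (`bins x bins`
#'   integer matrix), `h_edges`, `s_edges`, and `bluest_bin` (filled by
#'   [find_bluest_bin()]).
#' @export
build_phasor_histogram <- function(field, bins = 256) {
  stopifnot(inherits(field, "cmh_phasor_field"))
  if (!isTRUE(field$normalized)) {
    stop("histogram requires a normalized phasor field (fixed [-1,1] axes)",
         call. = FALSE)
  }
  if (!is.numeric(bins) || bins < 1) stop("`bins` must be >= 1", call. = FALSE)
  bins <- as.integer(bins)
  edges <- seq(-1, 1, length.out = bins + 1L)
  # column y from H=-1 upward; row x from S=+1 downward
  ycol <- bin_index(field$H, edges)
  xrow <- bins + 1L - bin_index(field$S, edges)
  counts <- matrix(0L, bins, bins)
  tab <- table(factor(xrow, levels = seq_len(bins)),
               factor(ycol, levels = seq_len(bins)))
  counts[] <- as.integer(tab)
  structure(list(counts = counts, h_edges = edges, s_edges = rev(edges),
                 bins = bins, pixel_size_um = field$pixel_size_um,
                 source_id = field$source_id),
            class = "cmh_phasor_histogram")
}

# index of the half-open bin [edge_i, edge_{i+1}); top edge closed
bin_index <- function(v, edges) {
  n <- length(edges) - 1L
  idx <- findInterval(v, edges, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), n)
}

#' Locate the bluest phasor-space bin
#'
#' Among occupied bins, returns the one minimising the index ratio `x/y`
#' (row over column, 1-based), the search rule that lands on the Prussian
#' blue cluster under this package's histogram orientation. Ties resolve to
#' the larger column, then the smaller row.
#'
#' @param hist A `cmh_phasor_histogram`.
#' @return The histogram with `bluest_bin = c(x, y)` and
#'   `bluest_center = c(H0, S0)` (bin-centre phasor coordinates) attached.
#' @export
find_bluest_bin <- function(hist) {
  stopifnot(inherits(hist, "cmh_phasor_histogram"))
  nz <- which(hist$counts > 0, arr.ind = TRUE)
  if (nrow(nz) == 0) stop("empty phasor histogram", call. = FALSE)
  ratio <- nz[, 1] / nz[, 2]
  best <- ratio == min(ratio)
  cand <- nz[best, , drop = FALSE]
  cand <- cand[order(-cand[, 2], cand[, 1]), , drop = FALSE]
  xy <- as.integer(cand[1, ])
  hist$bluest_bin <- xy
  hist$bluest_center <- bin_center(hist, xy[1], xy[2])
  hist
}

# phasor coordinates of the centre of bin (row x, col y)
bin_center <- function(hist, x, y) {
  step <- 2 / hist$bins
  H0 <- -1 + (y - 0.5) * step
  S0 <- 1 - (x - 0.5) * step
  c(H = H0, S = S0)
}

#' Circular phasor gate
#'
#' @param center Length-2 numeric `(H0, S0)`, usually the bluest-bin centre.
#' @param radius Gate radius in normalised phasor units; must be positive.
#' @return A `cmh_phasor_gate`.
#' @export
phasor_gate <- function(center, radius) {
  if (!is.numeric(center) || length(center) != 2L) {
    stop("`center` must be (H0, S0)", call. = FALSE)
  }
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    stop("`radius` must be a single positive number", call. = FALSE)
  }
  structure(list(center = as.numeric(center), radius = radius),
            class = "cmh_phasor_gate")
}

#' Remap a phasor gate to an image-space mask
#'
#' A pixel is segmented iff its phasor coordinate lies inside or on the
#' gate circle: \eqn{(H-H_0)^2 + (S-S_0)^2 \le r^2}. Masks are nested in the
#' radius.
#'
#' @param field A `cmh_phasor_field`.
#' @param gate A [phasor_gate()].
#' @return A [cmh_mask()].
#' @export
segment_by_phasor <- function(field, gate) {
  stopifnot(inherits(field, "cmh_phasor_field"), inherits(gate, "cmh_phasor_gate"))
  d2 <- (field$H - gate$center[1])^2 + (field$S - gate$center[2])^2
  cmh_mask(d2 <= gate$radius^2, field$pixel_size_um,
           source_id = field$source_id)
}

#' One-call phasor segmentation of an image
#'
#' Convenience wrapper: phasor transform, histogram, bluest-bin search, gate
#' at the given radius, remap. The gate centre is located per image, as the
#' method is self-referencing (no external calibration).
#'
#' @inheritParams compute_phasor
#' @param radius Gate radius in normalised phasor units.
#' @param bins Histogram bins per axis.
#' @return A [cmh_mask()].
#' @export
phasor_segment_image <- function(image, radius, bins = 256) {
  field <- compute_phasor(image, normalize = TRUE)
  hist <- find_bluest_bin(build_phasor_histogram(field, bins = bins))
  segment_by_phasor(field, phasor_gate(hist$bluest_center, radius))
}

#' Default radius grid
#'
#' 40 radii spanning `(0, 0.5]` in normalised phasor units.
#'
#' @param lo,hi Grid endpoints; `lo` exclusive of zero.
#' @param n Number of grid points.
#' @return Numeric vector of radii.
#' @export
phasor_radius_grid <- function(lo = 0.0125, hi = 0.5, n = 40) {
  stopifnot(lo > 0, hi > lo, n >= 2)
  seq(lo, hi, length.out = n)
}

#' Select the optimal phasor-gate radius on a dataset
#'
#' Mirrors [select_optimal_threshold()] but for the phasor method: per image,
#' the radius minimising the absolute percent error of the fully
#' post-processed segmented area against the ground truth; the dataset-level
#' optimum is the *mean* (not median) of the per-image bests.
#'
#' @inheritParams select_optimal_threshold
#' @param grid Radius grid; default [phasor_radius_grid()].
#' @param bins Histogram bins per axis.
#' @return A `cmh_radius_selection`: list with `optimal_radius`, tibble
#'   `per_image`, and the `grid`.
#' @export
select_optimal_radius <- function(data,
                                  grid = phasor_radius_grid(),
                                  chain_spec = filter_chain_spec("phasor"),
                                  rois = NULL,
                                  bins = 256) {
  sel <- select_optimal_parameter(
    data, grid, chain_spec, rois,
    segment_fun = phasor_segmenter(bins = bins),
    combine = mean
  )
  structure(list(optimal_radius = sel$optimal,
                 per_image = sel$per_image,
                 grid = grid),
            class = "cmh_radius_selection")
}

#' @export
print.cmh_radius_selection <- function(x, ...) {
  cat(sprintf("<radius selection> optimal phasor radius %.4g (mean of %d per-image bests)\n",
              x$optimal_radius, nrow(x$per_image)))
  invisible(x)
}
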