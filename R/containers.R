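#' Calibrated RGB image
#'
#' Constructs the package's basic image container: an `H x W x 3` array of
#' non-negative channel intensities (channel order red, green, blue) carrying
#' a physical pixel-size calibration. All segmentation functions take this
#' container as input.
#'
#' @param pixels Numeric `H x W x 3` array of non-negative intensities
#'   (8-bit `0..255` by default; 16-bit values are accepted as-is since both
#'   segmentation statistics are invariant to intensity scale).
#' @param pixel_size_um Physical edge length of one pixel in micrometres;
#'   must be positive. One pixel covers `pixel_size_um^2` square micrometres.
#' @param source_id Free-text identifier carried through to result tables.
#' @return An object of class `cmh_image`.
#' @export
cmh_image <- function(pixels, pixel_size_um, source_id = "image") {
  pixels <- unclass(pixels)
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("expected 3 channels: `pixels` must be an H x W x 3 array", call. = FALSE)
  }
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  check_pixel_size(pixel_size_um)
  structure(pixels,
            pixel_size_um = as.numeric(pixel_size_um),
            source_id = as.character(source_id),
            class = "cmh_image")
}

#' Calibrated binary mask
#'
#' A per-pixel foreground/background labelling on the same grid and physical
#' calibration as its paired image. Total physical area is
#' `sum(values) * pixel_size_um^2`.
#'
#' @param values Logical `H x W` matrix (or 0/1 numeric, coerced).
#' @inheritParams cmh_image
#' @return An object of class `cmh_mask`.
#' @export
cmh_mask <- function(values, pixel_size_um, source_id = "mask") {
  values <- unclass(values)
  if (is.numeric(values)) {
    if (any(!values %in% c(0, 1))) {
      stop("numeric mask values must be 0 or 1", call. = FALSE)
    }
    storage <- values != 0
    dim(storage) <- dim(values)
    values <- storage
  }
  if (!is.logical(values) || length(dim(values)) != 2L) {
    stop("`values` must be a logical H x W matrix", call. = FALSE)
  }
  if (anyNA(values)) stop("mask may not contain NA", call. = FALSE)
  check_pixel_size(pixel_size_um)
  structure(values,
            pixel_size_um = as.numeric(pixel_size_um),
            source_id = as.character(source_id),
            class = "cmh_mask")
}

check_pixel_size <- function(pixel_size_um) {
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  }
  invisible(pixel_size_um)
}

#' @export
print.cmh_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<cmh_image> %d x %d px, %.4g um/px, id '%s'\n",
              d[1], d[2], pixel_size(x), source_id(x)))
  invisible(x)
}

#' @export
print.cmh_mask <- function(x, ...) {
  cat(sprintf("<cmh_mask> %d x %d px, %.4g um/px, %d fg px (%.4g um^2), id '%s'\n",
              nrow(x), ncol(x), pixel_size(x), sum(x), mask_area_um2(x),
              source_id(x)))
  invisible(x)
}

#' Pixel-size and identifier accessors
#'
#' @param x A `cmh_image` or `cmh_mask`.
#' @return `pixel_size()` the calibration in micrometres per pixel edge;
#'   `source_id()` the identifier string.
#' @export
pixel_size <- function(x) attr(x, "pixel_size_um")

#' @rdname pixel_size
#' @export
source_id <- function(x) attr(x, "source_id")

#' Physical foreground area of a mask
#'
#' @param mask A `cmh_mask`.
#' @return Total foreground area in square micrometres:
#'   foreground pixel count times the squared pixel size.
#' @export
mask_area_um2 <- function(mask) {
  stopifnot(inherits(mask, "cmh_mask"))
  sum(mask) * pixel_size(mask)^2
}

# one colour channel as an H x W matrix (no dimension dropping on W = 1)
channel <- function(px, i) {
  m <- px[, , i, drop = FALSE]
  dim(m) <- dim(px)[1:2]
  m
}

# logical matrix view without the class/attrs (for arithmetic)
mask_values <- function(mask) {
  v <- unclass(mask)
  attributes(v) <- list(dim = dim(v))
  v
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    stop("masks/images must share the same H x W grid", call. = FALSE)
  }
  if (!isTRUE(all.equal(pixel_size(a), pixel_size(b)))) {
    stop("masks/images must share the same pixel-size calibration", call. = FALSE)
  }
  invisible(TRUE)
}
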