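#' Read a calibrated RGB image
#'
#' Reads a 3-channel PNG or TIFF into a [cmh_image()]. Channel order in the
#' returned array is always red, green, blue. Intensities are rescaled from
#' the reader's `[0, 1]` convention back to integer counts (8-bit by default,
#' 16-bit respected for 16-bit TIFF/PNG).
#'
#' @param path Path to a 3-channel PNG or TIFF file.
#' @param pixel_size_um Calibration in micrometres per pixel edge. Required:
#'   there is no meaningful default, physical-area filters depend on it.
#' @param source_id Identifier; defaults to the file name.
#' @return A [cmh_image()].
#' @export
read_image <- function(path, pixel_size_um, source_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  check_pixel_size(pixel_size_um)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)", call. = FALSE)
  )
  if (length(dim(raw)) == 3L && dim(raw)[3] == 4L) raw <- raw[, , 1:3, drop = FALSE]
  if (length(dim(raw)) != 3L || dim(raw)[3] != 3L) {
    stop("expected 3 channels in ", path, call. = FALSE)
  }
  # readers return [0,1]; recover integer counts (8-bit unless finer steps seen)
  bits <- if (any(abs(raw * 255 - round(raw * 255)) > 1e-6)) 65535 else 255
  cmh_image(round(raw * bits), pixel_size_um, source_id = source_id)
}

#' Write and read binary masks as PNG
#'
#' Foreground is stored as 255, background as 0. Reading refuses any other
#' grey level so silently thresholded masks cannot slip through.
#'
#' @param mask A [cmh_mask()].
#' @param path Output/input PNG path.
#' @return `write_mask_png()` returns `path` invisibly; `read_mask_png()`
#'   returns a [cmh_mask()].
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "cmh_mask"))
  png::writePNG(mask_values(mask) * 1.0, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @inheritParams read_image
#' @export
read_mask_png <- function(path, pixel_size_um, source_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1]
  vals <- round(raw * 255)
  if (!all(vals %in% c(0, 255))) {
    stop("mask PNG must contain only values 0 and 255: ", path, call. = FALSE)
  }
  cmh_mask(vals == 255, pixel_size_um, source_id = source_id)
}

#' Run-length encode a binary mask
#'
#' Encodes foreground runs over the row-major (row 1 left to right, then row
#' 2, ...) 0-based flattened pixel order, the compact text format used to
#' store annotation masks. `rle_decode()` inverts it exactly.
#'
#' @param mask A [cmh_mask()].
#' @return A list with `shape = c(H, W)` and `runs`, an `n x 2` matrix of
#'   `(start_offset, length)` pairs (0-based, sorted, non-overlapping).
#' @export
rle_encode <- function(mask) {
  stopifnot(inherits(mask, "cmh_mask"))
  v <- as.vector(t(mask_values(mask)))  # row-major flatten
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based
  keep <- r$values
  runs <- cbind(start = starts[keep], length = r$lengths[keep])
  list(shape = dim(mask), runs = runs)
}

#' @rdname rle_encode
#' @param rle A list as returned by `rle_encode()`.
#' @inheritParams read_image
#' @export
rle_decode <- function(rle, pixel_size_um, source_id = "rle") {
  shape <- as.integer(rle$shape)
  n <- prod(shape)
  v <- logical(n)
  runs <- rle$runs
  if (length(runs)) {
    runs <- matrix(as.numeric(runs), ncol = 2)
    if (any(runs[, 1] < 0) || any(runs[, 2] < 1) ||
        any(runs[, 1] + runs[, 2] > n)) {
      stop("runs exceed mask extent H*W", call. = FALSE)
    }
    for (i in seq_len(nrow(runs))) {
      v[(runs[i, 1] + 1):(runs[i, 1] + runs[i, 2])] <- TRUE
    }
  }
  m <- matrix(v, nrow = shape[1], byrow = TRUE)
  cmh_mask(m, pixel_size_um, source_id = source_id)
}

#' Read/write run-length masks as JSON
#'
#' Serialises the [rle_encode()] representation as
#' `{"shape":[H,W],"runs":[[start,length],...]}`.
#'
#' @inheritParams write_mask_png
#' @inheritParams read_image
#' @export
write_mask_rle <- function(mask, path) {
  enc <- rle_encode(mask)
  runs <- lapply(seq_len(nrow(enc$runs)), function(i) as.integer(enc$runs[i, ]))
  jsonlite::write_json(list(shape = as.integer(enc$shape), runs = runs),
                       path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_mask_rle
#' @export
read_mask_rle <- function(path, pixel_size_um, source_id = basename(path)) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  runs <- obj$runs
  if (is.null(runs) || length(runs) == 0) {
    runs <- matrix(numeric(0), ncol = 2)
  } else if (!is.matrix(runs)) {
    runs <- matrix(unlist(runs), ncol = 2, byrow = TRUE)
  }
  rle_decode(list(shape = obj$shape, runs = runs), pixel_size_um,
             source_id = source_id)
}

#' Write a per-image area/metric table
#'
#' One row per (image, method) with the segmentation parameter, the segmented
#' and ground-truth areas in square micrometres, and their percent
#' difference. Values are echoed bit-exactly; the CSV always carries a
#' header, even for an empty record set.
#'
#' @param records A data frame (possibly 0-row) with columns `image_id`,
#'   `method`, `parameter`, `segmented_area_um2`, `truth_area_um2`,
#'   `percent_error`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_area_table <- function(records, path) {
  cols <- c("image_id", "method", "parameter",
            "segmented_area_um2", "truth_area_um2", "percent_error")
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0 && ncol(records) == 0) {
    records <- tibble::as_tibble(stats::setNames(
      rep(list(character(0)), length(cols)), cols))
  }
  missing <- setdiff(cols, names(records))
  if (length(missing)) {
    stop("records are missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(records[cols], path)
  invisible(path)
}
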