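# Small constructors used across the suite.

# logical matrix -> calibrated mask
mk_mask <- function(m, ps = 0.5) cmh_mask(matrix(as.logical(m), nrow(m), ncol(m)), ps)

# empty H x W mask with optional solid rectangles: list(c(r1, r2, c1, c2), ...)
rect_mask <- function(h, w, rects = list(), ps = 0.5) {
  m <- matrix(FALSE, h, w)
  for (r in rects) m[r[1]:r[2], r[3]:r[4]] <- TRUE
  cmh_mask(m, ps)
}

# uniform-colour image
flat_image <- function(h, w, rgb, ps = 0.5) {
  cmh_image(array(rep(rgb, each = h * w), dim = c(h, w, 3)), ps)
}

# random mask with given foreground probability
random_mask <- function(h, w, p = 0.3, ps = 0.5) {
  cmh_mask(matrix(runif(h * w) < p, h, w), ps)
}

# random 8-bit image
random_image <- function(h, w, ps = 0.5) {
  cmh_image(array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3)), ps)
}

# tiny seeded dataset for pipeline-level tests
tiny_dataset <- function(n = 3, seed = 99, n_shadows = 0, shape = c(96, 96),
                         areas = c(30, 800)) {
  spec <- synthetic_spec(image_shape = shape, n_blobs = 2,
                         area_range_um2 = areas, n_shadows = n_shadows)
  generate_dataset(n, spec, seed = seed)
}
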