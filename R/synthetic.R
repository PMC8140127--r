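#' Synthetic histology specification
#'
#' Settings for the seeded generator of histology-like fixtures: irregular
#' Prussian-blue-like blobs (blue-dominant, low segmentation ratio) on a
#' Nuclear-Fast-Red-like pink background (red-dominant, ratio above 1), with
#' per-pixel Gaussian noise, soft anti-aliased blob edges, and optional
#' near-achromatic shadow artifacts that belong to no true deposit. Blob
#' areas are log-uniform over `area_range_um2`, whose default spans the
#' 5-6000 um^2 post-processing bounds.
#'
#' @param image_shape `(H, W)` in pixels.
#' @param pixel_size_um Micrometres per pixel edge.
#' @param n_blobs Number of true deposits per image.
#' @param area_range_um2 Log-uniform blob-area range, square micrometres.
#' @param blob_rgb,blob_noise_sd Mean RGB of deposit pixels and the Gaussian
#'   channel noise standard deviation there (8-bit counts).
#' @param bg_rgb,bg_noise_sd Background counterpart.
#' @param edge_softness_px Width of the anti-aliased blob edge in pixels.
#' @param n_shadows Achromatic shadow patches per image (0 disables).
#' @param shadow_rgb Mean RGB of shadow pixels (achromatic by default, so
#'   their ratio is about 1 and their phasor sits near the origin).
#' @param shadow_area_um2 Shadow patch area range, square micrometres.
#' @return A `cmh_synth_spec`.
#' @export
synthetic_spec <- function(image_shape = c(256, 256),
                           pixel_size_um = 0.75,
                           n_blobs = 3,
                           area_range_um2 = c(5, 6000),
                           blob_rgb = c(50, 50, 210),
                           blob_noise_sd = 8,
                           bg_rgb = c(220, 140, 170),
                           bg_noise_sd = 8,
                           edge_softness_px = 1.5,
                           n_shadows = 0,
                           shadow_rgb = c(120, 120, 120),
                           shadow_area_um2 = c(200, 2000)) {
  check_pixel_size(pixel_size_um)
  stopifnot(length(image_shape) == 2, all(image_shape >= 8),
            n_blobs >= 0, all(area_range_um2 > 0),
            area_range_um2[1] <= area_range_um2[2],
            n_shadows >= 0)
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size_um = pixel_size_um,
                 n_blobs = as.integer(n_blobs),
                 area_range_um2 = area_range_um2,
                 blob_rgb = blob_rgb, blob_noise_sd = blob_noise_sd,
                 bg_rgb = bg_rgb, bg_noise_sd = bg_noise_sd,
                 edge_softness_px = edge_softness_px,
                 n_shadows = as.integer(n_shadows),
                 shadow_rgb = shadow_rgb,
                 shadow_area_um2 = shadow_area_um2),
            class = "cmh_synth_spec")
}

# One deformed-ellipse patch: alpha in [0,1] over a bounding box.
# Shapes are ellipses with low-frequency radial perturbation and a soft
# anti-aliased edge; compact but irregular, like iron deposits.
sample_blob_patch <- function(area_um2, pixel_size_um, edge_softness_px) {
  area_px <- area_um2 / pixel_size_um^2
  q <- stats::runif(1, 0.55, 1)                 # axis ratio
  a <- sqrt(area_px / (pi * q)); b <- q * a      # semi-axes, px
  theta <- stats::runif(1, 0, pi)
  amp <- stats::runif(2, 0, 0.15)
  ph <- stats::runif(2, 0, 2 * pi)
  rmax <- max(a, b) * (1 + sum(amp)) + edge_softness_px + 1
  half <- ceiling(rmax)
  n <- 2L * half + 1L
  off <- seq(-half, half)
  xx <- matrix(off, n, n, byrow = TRUE)   # column offset
  yy <- matrix(off, n, n)                 # row offset
  xr <- cos(theta) * xx + sin(theta) * yy
  yr <- -sin(theta) * xx + cos(theta) * yy
  rho <- sqrt((xr / a)^2 + (yr / b)^2)
  phi <- atan2(yr / b, xr / a)
  rb <- 1 + amp[1] * sin(2 * phi + ph[1]) + amp[2] * sin(3 * phi + ph[2])
  # approximate signed distance to the boundary in pixels
  sd_px <- (rb - rho) * min(a, b)
  alpha <- pmin(pmax(sd_px / edge_softness_px + 0.5, 0), 1)
  list(alpha = alpha, half = half, rmax = rmax)
}

#' Generate one synthetic histology image
#'
#' Deterministic given `seed`: composites `n_blobs` deformed-ellipse blue
#' deposits (and optionally achromatic shadow patches, which are *not* part
#' of the truth) over the pink background, blends colours across the soft
#' blob edge, then adds per-pixel Gaussian channel noise and clips to 8-bit.
#' The truth mask is the set of pixels whose blob coverage is at least one
#' half (the anti-aliased boundary's midline).
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; same seed, same bytes.
#' @param image_id Identifier attached to the image, truth and catalog.
#' @return List: `image` ([cmh_image()]), `truth` ([cmh_mask()]), `shadow`
#'   (a [cmh_mask()] of shadow-artifact pixels, disjoint from the truth),
#'   and `catalog`, a tibble of patches (`patch`, `row`, `col`,
#'   `requested_area_um2`, `realized_area_um2`, `is_shadow`).
#' @export
generate_image <- function(spec, seed, image_id = paste0("synth-", seed)) {
  stopifnot(inherits(spec, "cmh_synth_spec"))
  withr::with_seed(as.integer(seed), generate_image_impl(spec, image_id))
}

generate_image_impl <- function(spec, image_id) {
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  base <- array(rep(spec$bg_rgb, each = h * w), dim = c(h, w, 3))
  alpha_truth <- matrix(0, h, w)   # blob coverage
  alpha_shadow <- matrix(0, h, w)
  cat_rows <- list()
  place <- function(area_um2, avoid = NULL) {
    patch <- sample_blob_patch(area_um2, spec$pixel_size_um,
                               spec$edge_softness_px)
    half <- patch$half
    if (2 * half + 1 > min(h, w)) {
      stop("blob area ", round(area_um2), " um^2 incompatible with image size",
           call. = FALSE)
    }
    for (try in 1:25) {
      cr <- sample(seq(half + 1, h - half), 1)
      cc <- sample(seq(half + 1, w - half), 1)
      rows <- (cr - half):(cr + half); cols <- (cc - half):(cc + half)
      if (is.null(avoid) || all(avoid[rows, cols][patch$alpha > 0] == 0)) {
        return(list(patch = patch, rows = rows, cols = cols,
                    center = c(cr, cc)))
      }
    }
    NULL  # could not place without overlap
  }
  # true deposits: placed without overlap (deposits are distinct; merged
  # draws would form regions beyond the large-area removal bound), largest
  # first so big blobs are not crowded out
  if (spec$n_blobs > 0) {
    areas <- sort(exp(stats::runif(spec$n_blobs, log(spec$area_range_um2[1]),
                                   log(spec$area_range_um2[2]))),
                  decreasing = TRUE)
    for (i in seq_len(spec$n_blobs)) {
      p <- place(areas[i], avoid = alpha_truth)
      if (is.null(p)) next
      al <- p$patch$alpha
      alpha_truth[p$rows, p$cols] <- pmax(alpha_truth[p$rows, p$cols], al)
      cat_rows[[length(cat_rows) + 1L]] <- tibble::tibble(
        patch = length(cat_rows) + 1L, row = p$center[1], col = p$center[2],
        requested_area_um2 = areas[i],
        realized_area_um2 = sum(al >= 0.5) * spec$pixel_size_um^2,
        is_shadow = FALSE)
    }
  }
  # shadow artifacts: placed off the deposits, excluded from truth
  if (spec$n_shadows > 0) {
    for (i in seq_len(spec$n_shadows)) {
      area <- exp(stats::runif(1, log(spec$shadow_area_um2[1]),
                               log(spec$shadow_area_um2[2])))
      p <- place(area, avoid = alpha_truth)
      if (is.null(p)) next
      al <- p$patch$alpha
      alpha_shadow[p$rows, p$cols] <- pmax(alpha_shadow[p$rows, p$cols], al)
      cat_rows[[length(cat_rows) + 1L]] <- tibble::tibble(
        patch = length(cat_rows) + 1L, row = p$center[1], col = p$center[2],
        requested_area_um2 = area,
        realized_area_um2 = sum(al >= 0.5) * spec$pixel_size_um^2,
        is_shadow = TRUE)
    }
  }
  for (ch in 1:3) {
    base[, , ch] <- base[, , ch] * (1 - alpha_shadow) +
      spec$shadow_rgb[ch] * alpha_shadow
    base[, , ch] <- base[, , ch] * (1 - alpha_truth) +
      spec$blob_rgb[ch] * alpha_truth
  }
  noise_sd <- alpha_truth * spec$blob_noise_sd +
    (1 - alpha_truth) * spec$bg_noise_sd
  noise <- array(stats::rnorm(h * w * 3), dim = c(h, w, 3)) *
    array(rep(noise_sd, 3), dim = c(h, w, 3))
  px <- pmin(pmax(round(base + noise), 0), 255)
  catalog <- if (length(cat_rows)) dplyr::bind_rows(cat_rows) else
    tibble::tibble(patch = integer(), row = integer(), col = integer(),
                   requested_area_um2 = numeric(),
                   realized_area_um2 = numeric(), is_shadow = logical())
  list(image = cmh_image(px, spec$pixel_size_um, source_id = image_id),
       truth = cmh_mask(alpha_truth >= 0.5, spec$pixel_size_um,
                        source_id = image_id),
       shadow = cmh_mask(alpha_shadow >= 0.5, spec$pixel_size_um,
                         source_id = paste0(image_id, "-shadow")),
       catalog = catalog)
}

#' Simulate independent annotators
#'
#' Each annotator redraws every truth region with a boundary perturbed by a
#' morphological dilation or erosion of radius up to `jitter_px` (disc
#' structuring element, radius drawn uniformly from
#' `-jitter_px ... +jitter_px` per region per annotator), and may miss small
#' regions entirely (`miss_prob`, applied to regions below `miss_area_um2`).
#' With `jitter_px = 0` and `miss_prob = 0` every annotator reproduces the
#' truth exactly, and any annotator mask is contained in the
#' `jitter_px`-dilation of the truth.
#'
#' @param truth A [cmh_mask()].
#' @param k Number of annotators.
#' @param jitter_px Maximum boundary dilation/erosion radius in pixels.
#' @param miss_prob Probability an annotator misses a small region.
#' @param miss_area_um2 Regions below this area are miss-eligible.
#' @param seed Integer seed.
#' @return List of `k` [cmh_mask()] objects.
#' @export
generate_annotations <- function(truth, k = 4, jitter_px = 1,
                                 miss_prob = 0.1, miss_area_um2 = 20,
                                 seed = 1) {
  stopifnot(inherits(truth, "cmh_mask"), k >= 1, jitter_px >= 0,
            miss_prob >= 0, miss_prob <= 1)
  withr::with_seed(as.integer(seed), {
    regions <- label_regions(truth)
    lapply(seq_len(k), function(a) {
      m <- matrix(FALSE, nrow(truth), ncol(truth))
      for (i in seq_len(nrow(regions$regions))) {
        info <- regions$regions[i, ]
        if (info$area_um2 < miss_area_um2 && stats::runif(1) < miss_prob) next
        rm_ <- regions$labels == info$label
        delta <- if (jitter_px > 0) sample(-jitter_px:jitter_px, 1) else 0L
        if (delta != 0) {
          brush <- EBImage::makeBrush(2L * abs(delta) + 1L, "disc")
          rm_ <- if (delta > 0) {
            EBImage::dilate(rm_ * 1, brush) > 0
          } else {
            EBImage::erode(rm_ * 1, brush) > 0
          }
        }
        m <- m | rm_
      }
      cmh_mask(m, pixel_size(truth),
               source_id = paste0(source_id(truth), "-annotator", a))
    })
  })
}

#' Generate a reproducible synthetic dataset
#'
#' Draws one sub-seed per image from the master seed, generates each image,
#' its truth mask, its annotator masks, and (optionally) writes everything
#' to a directory as PNGs plus a manifest CSV of per-image seeds and patch
#' catalogs. Re-running with the same seed reproduces the dataset
#' byte-for-byte.
#'
#' @param n_images Number of images.
#' @param spec A [synthetic_spec()].
#' @param seed Master integer seed.
#' @param k_annotators,jitter_px,miss_prob Passed to
#'   [generate_annotations()].
#' @param dir Optional output directory; created if missing.
#' @return A dataset tibble with one row per image: `image_id`, `seed`, and
#'   list-columns `image`, `truth`, `annotations`, `catalog`.
#' @export
generate_dataset <- function(n_images, spec = synthetic_spec(), seed = 1,
                             k_annotators = 4, jitter_px = 1,
                             miss_prob = 0.1, dir = NULL) {
  stopifnot(n_images >= 0)
  sub_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(.Machine$integer.max - 1L, n_images))
  rows <- purrr::map(seq_len(n_images), function(i) {
    id <- sprintf("synth-%03d", i)
    g <- generate_image(spec, sub_seeds[i], image_id = id)
    ann <- generate_annotations(g$truth, k = k_annotators,
                                jitter_px = jitter_px, miss_prob = miss_prob,
                                seed = sub_seeds[i] %% 100000000L + 1L)
    tibble::tibble(image_id = id, seed = sub_seeds[i],
                   image = list(g$image), truth = list(g$truth),
                   shadow = list(g$shadow),
                   annotations = list(ann), catalog = list(g$catalog))
  })
  data <- if (n_images > 0) dplyr::bind_rows(rows) else
    tibble::tibble(image_id = character(), seed = integer(),
                   image = list(), truth = list(), shadow = list(),
                   annotations = list(), catalog = list())
  if (!is.null(dir)) write_dataset(data, spec, dir)
  data
}

write_dataset <- function(data, spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(data))) {
    id <- data$image_id[i]
    img <- data$image[[i]]
    png::writePNG(unclass(img) / 255, file.path(dir, paste0(id, ".png")))
    write_mask_png(data$truth[[i]], file.path(dir, paste0(id, "_truth.png")))
    anns <- data$annotations[[i]]
    for (a in seq_along(anns)) {
      write_mask_png(anns[[a]],
                     file.path(dir, sprintf("%s_annotator%d.png", id, a)))
    }
  }
  manifest <- dplyr::bind_rows(purrr::map(seq_len(nrow(data)), function(i) {
    cat <- data$catalog[[i]]
    if (nrow(cat) == 0) return(NULL)
    dplyr::bind_cols(tibble::tibble(image_id = data$image_id[i],
                                    seed = data$seed[i])[rep(1, nrow(cat)), ],
                     cat)
  }))
  if (is.null(manifest) || nrow(manifest) == 0) {
    manifest <- tibble::tibble(image_id = character(), seed = integer(),
                               patch = integer(), row = integer(),
                               col = integer(), requested_area_um2 = numeric(),
                               realized_area_um2 = numeric(),
                               is_shadow = logical())
  }
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  yaml::write_yaml(list(pixel_size_um = spec$pixel_size_um,
                        image_shape = spec$image_shape,
                        n_images = nrow(data)),
                   file.path(dir, "dataset.yaml"))
  invisible(dir)
}
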