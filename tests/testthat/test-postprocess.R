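test_that("labelling respects connectivity and physical areas", {
  diag2 <- mk_mask(rbind(c(1, 0), c(0, 1)))
  expect_equal(nrow(label_regions(diag2, connectivity = 8)$regions), 1)
  expect_equal(nrow(label_regions(diag2, connectivity = 4)$regions), 2)

  expect_equal(nrow(label_regions(rect_mask(4, 4))$regions), 0)

  block <- rect_mask(5, 5, list(c(2, 4, 2, 4)), ps = 0.5)
  reg <- label_regions(block)
  expect_equal(reg$regions$area_um2, 9 * 0.25)
  expect_equal(max(reg$labels), 1)
})

test_that("small-region removal applies the strict 5 um^2 rule", {
  # at 0.5 um/px: 18 px = 4.5 um^2 (removed), 21 px = 5.25 um^2 (kept)
  m <- rect_mask(20, 20, list(c(2, 4, 2, 7),     # 3x6 = 18 px
                              c(10, 12, 10, 16)), # 3x7 = 21 px
                 ps = 0.5)
  out <- remove_small(m, 5)
  reg <- label_regions(out)
  expect_equal(reg$regions$area_um2, 5.25)

  # exactly 5 um^2 (20 px) is kept: strict "less than"
  exact <- rect_mask(10, 10, list(c(2, 5, 2, 6)), ps = 0.5)  # 4x5 = 20 px
  expect_equal(mask_area_um2(remove_small(exact, 5)), 5)

  expect_equal(sum(mask_values(remove_small(rect_mask(5, 5), 5))), 0)
})

test_that("isolated-speckle rule removes only small far-away regions", {
  ps <- 1
  # 10 um^2 region 60 um from its only neighbour -> removed
  far <- rect_mask(100, 100, list(c(1, 2, 1, 5),      # 10 px = 10 um^2
                                  c(80, 89, 70, 79)), # 100 um^2 anchor
                   ps = ps)
  out <- remove_isolated_small(far, 50, 50)
  expect_equal(mask_area_um2(out), 100)

  # same small region 30 um from the neighbour -> kept
  near <- rect_mask(100, 100, list(c(1, 2, 1, 5), c(33, 42, 1, 10)), ps = ps)
  expect_equal(mask_area_um2(remove_isolated_small(near, 50, 50)), 110)

  # 80 um^2 region 200 um from anything -> kept (fails the area clause)
  big <- rect_mask(250, 250, list(c(1, 8, 1, 10), c(240, 249, 240, 249)),
                   ps = ps)
  expect_equal(mask_area_um2(remove_isolated_small(big, 50, 50)), 180)

  # a single small region is kept: no closest spot exists
  lone <- rect_mask(100, 100, list(c(1, 2, 1, 5)), ps = ps)
  expect_equal(mask_area_um2(remove_isolated_small(lone, 50, 50)), 10)
})

test_that("isolation distance is boundary-to-boundary, not centroid", {
  ps <- 1
  # gap between region edges is 46 um (kept) though centroids are ~51 apart
  m <- rect_mask(120, 120, list(c(1, 10, 1, 10), c(56, 57, 1, 4)), ps = ps)
  expect_equal(mask_area_um2(remove_isolated_small(m, 50, 50)), 108)
  # push the small region so the edge gap exceeds 50 um -> removed
  m2 <- rect_mask(120, 120, list(c(1, 10, 1, 10), c(62, 63, 1, 4)), ps = ps)
  expect_equal(mask_area_um2(remove_isolated_small(m2, 50, 50)), 100)
})

test_that("large-region removal applies the strict 6000 um^2 rule", {
  ps <- 1
  over <- rect_mask(120, 120, list(c(1, 77, 1, 78), c(100, 109, 100, 109)),
                    ps = ps)  # 77*78 = 6006 um^2 and a 100 um^2 region
  expect_equal(mask_area_um2(remove_large(over, 6000)), 100)

  at <- rect_mask(120, 120, list(c(1, 75, 1, 80)), ps = ps)  # exactly 6000
  expect_equal(mask_area_um2(remove_large(at, 6000)), 6000)

  expect_equal(mask_area_um2(remove_large(rect_mask(5, 5, ps = ps))), 0)
})

test_that("hole filling adds only small strictly interior holes", {
  ps <- 0.5
  # 1-px hole (0.25 um^2) inside a blob -> filled
  blob <- rect_mask(9, 9, list(c(2, 8, 2, 8)), ps = ps)
  holed <- mask_values(blob); holed[5, 5] <- FALSE
  filled <- fill_small_holes(cmh_mask(holed, ps), 1.73)
  expect_true(mask_values(filled)[5, 5])
  expect_equal(mask_area_um2(filled), mask_area_um2(blob))

  # 3x3 hole (2.25 um^2) -> not filled
  big <- mask_values(rect_mask(11, 11, list(c(2, 10, 2, 10)), ps = ps))
  big[5:7, 5:7] <- FALSE
  out <- fill_small_holes(cmh_mask(big, ps), 1.73)
  expect_false(any(mask_values(out)[5:7, 5:7]))

  # border-touching background is exterior, never filled
  edge <- matrix(TRUE, 5, 5); edge[1, 3] <- FALSE
  out2 <- fill_small_holes(cmh_mask(edge, ps), 1.73)
  expect_false(mask_values(out2)[1, 3])
})

test_that("ROI check intersects and the chain wires steps per method", {
  m <- rect_mask(30, 30, list(c(2, 11, 2, 11), c(20, 25, 20, 25)), ps = 1)
  all_true <- cmh_mask(matrix(TRUE, 30, 30), 1)
  expect_identical(mask_values(apply_roi_check(m, all_true)), mask_values(m))
  expect_equal(sum(mask_values(apply_roi_check(m, rect_mask(30, 30, ps = 1)))), 0)
  roi <- rect_mask(30, 30, list(c(1, 15, 1, 15)), ps = 1)
  expect_equal(mask_area_um2(apply_roi_check(m, roi)), 100)

  # ground-truth chain skips the large-area removal
  huge <- rect_mask(120, 120, list(c(1, 80, 1, 80)), ps = 1)  # 6400 um^2
  expect_equal(mask_area_um2(run_chain(huge, filter_chain_spec("truth"))), 6400)
  expect_equal(mask_area_um2(run_chain(huge, filter_chain_spec("ratiometric"))), 0)

  # chain with an all-true ROI equals the chain without one
  spec <- filter_chain_spec("phasor")
  withr::local_seed(71)
  rm_ <- random_mask(40, 40, p = 0.4, ps = 1)
  all40 <- cmh_mask(matrix(TRUE, 40, 40), 1)
  expect_identical(mask_values(run_chain(rm_, spec, roi = all40)),
                   mask_values(run_chain(rm_, spec)))
  expect_equal(sum(mask_values(run_chain(rect_mask(20, 20, ps = 1), spec))), 0)
})

test_that("removal steps are subset-preserving and the chain is idempotent", {
  withr::local_seed(73)
  spec <- filter_chain_spec("ratiometric")
  for (i in 1:25) {
    m <- random_mask(48, 48, p = runif(1, 0.1, 0.5), ps = 1)
    out <- run_chain(m, spec)
    expect_true(all(mask_values(m)[mask_values(out)]))       # subset
    again <- run_chain(out, spec)
    expect_identical(mask_values(again), mask_values(out))   # idempotent
  }
  # phasor chain may add hole pixels on the first pass; second pass is stable
  pspec <- filter_chain_spec("phasor")
  for (i in 1:10) {
    m <- random_mask(48, 48, p = 0.45, ps = 1)
    once <- run_chain(m, pspec)
    extra <- mask_values(once) & !mask_values(m)
    if (any(extra)) {  # added pixels must be interior (not on the border)
      idx <- which(extra, arr.ind = TRUE)
      expect_true(all(idx > 1 & idx < 48))
    }
    expect_identical(mask_values(run_chain(once, pspec)), mask_values(once))
  }
})

test_that("filters are calibration-correct for solid blocks", {
  # blocks of identical physical area at two calibrations get the same
  # keep/remove decision
  fine <- rect_mask(20, 20, list(c(2, 5, 2, 6)), ps = 0.5)    # 20 px = 5 um^2
  coarse <- rect_mask(10, 10, list(c(2, 2, 2, 6)), ps = 1)    # 5 px  = 5 um^2
  expect_equal(mask_area_um2(remove_small(fine, 5)), 5)
  expect_equal(mask_area_um2(remove_small(coarse, 5)), 5)
  # shrink below the bound at both calibrations
  fine2 <- rect_mask(20, 20, list(c(2, 4, 2, 7)), ps = 0.5)   # 18 px = 4.5
  coarse2 <- rect_mask(10, 10, list(c(2, 3, 2, 3)), ps = 1)   # 4 px = 4
  expect_equal(mask_area_um2(remove_small(fine2, 5)), 0)
  expect_equal(mask_area_um2(remove_small(coarse2, 5)), 0)
})

test_that("filter settings validate and tag the method", {
  expect_error(filter_chain_spec("ratiometric", min_area_um2 = -1), "positive")
  expect_error(filter_chain_spec("unknown"))
  s <- filter_chain_spec("phasor")
  expect_equal(s$min_area_um2, 5)
  expect_equal(s$isolated_max_area_um2, 50)
  expect_equal(s$isolation_distance_um, 50)
  expect_equal(s$max_area_um2, 6000)
  expect_equal(s$hole_fill_max_um2, 1.73)
})
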