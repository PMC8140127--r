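test_that("confusion counts match a brute-force pixel loop", {
  withr::local_seed(91)
  for (i in 1:20) {
    pred <- random_mask(16, 16, p = runif(1, 0.2, 0.8))
    truth <- random_mask(16, 16, p = runif(1, 0.2, 0.8))
    cc <- confusion(pred, truth)
    tp <- fp <- tn <- fn <- 0
    for (r in 1:16) for (c in 1:16) {
      p <- mask_values(pred)[r, c]; t <- mask_values(truth)[r, c]
      if (p && t) tp <- tp + 1 else if (p && !t) fp <- fp + 1
      else if (!p && t) fn <- fn + 1 else tn <- tn + 1
    }
    expect_equal(unlist(cc), c(tp = tp, fp = fp, tn = tn, fn = fn))
    expect_equal(sum(unlist(cc)), 256)
  }
  m <- random_mask(8, 8, 0.5)
  ident <- confusion(m, m)
  expect_equal(ident$fp + ident$fn, 0)
  inv <- confusion(m, cmh_mask(!mask_values(m), 0.5))
  expect_equal(inv$tp + inv$tn, 0)
})

test_that("sensitivity and specificity follow their defining ratios", {
  cc <- tibble::tibble(tp = 80, fn = 20, tn = 990, fp = 10)
  expect_equal(sensitivity_specificity(cc),
               c(sensitivity = 0.8, specificity = 0.99))
  expect_error(sensitivity_specificity(tibble::tibble(tp = 0, fn = 0, tn = 5,
                                                      fp = 5)),
               "sensitivity undefined")
  expect_error(sensitivity_specificity(tibble::tibble(tp = 5, fn = 5, tn = 0,
                                                      fp = 0)),
               "specificity undefined")
  # pooling across rows equals summing counts first
  parts <- tibble::tibble(tp = c(10, 70), fn = c(15, 5), tn = c(500, 490),
                          fp = c(4, 6))
  expect_equal(sensitivity_specificity(parts),
               c(sensitivity = 80 / 100, specificity = 990 / 1000))
})

test_that("Dice handles identity, disjoint, partial and empty cases", {
  a <- rect_mask(10, 10, list(c(1, 10, 1, 10)))
  expect_equal(dice(a, a), 1)
  b <- rect_mask(10, 10, list(c(1, 5, 1, 10)))
  d <- rect_mask(10, 10, list(c(6, 10, 1, 10)))
  expect_equal(dice(b, d), 0)
  expect_equal(dice(a, b), 2 * 50 / 150)
  empty <- rect_mask(10, 10)
  expect_equal(dice(empty, empty), 1)
})

test_that("percent error is signed and guards the denominator", {
  expect_equal(percent_error(90, 100), -10)
  expect_equal(percent_error(100, 100), 0)
  expect_equal(percent_error(150, 100), 50)
  expect_error(percent_error(10, 0), "positive")
})

test_that("truth-returning and truth-independent segmenters bracket the AUC", {
  withr::local_seed(97)
  data <- tibble::tibble(
    image_id = as.character(1:3),
    image = purrr::map(1:3, function(i) {
      img <- random_image(24, 24, ps = 1)
      attr(img, "source_id") <- as.character(i)
      img
    }),
    truth = purrr::map(1:3, ~ random_mask(24, 24, p = 0.3, ps = 1)))

  oracle <- function(image, p) {
    data$truth[[match(source_id(image), data$image_id)]]
  }
  roc1 <- roc_sweep(data, oracle, grid = c(0.2, 0.5, 0.8),
                    partial_chain = FALSE)
  expect_equal(roc1$auc, 1.0)
  expect_true(all(tidy(roc1)$sensitivity == 1))
  expect_true(all(tidy(roc1)$specificity == 1))

  aucs <- vapply(1:20, function(s) {
    rand_seg <- function(image, p) {
      cmh_mask(matrix(runif(24 * 24) < p, 24, 24), 1)
    }
    withr::with_seed(1000 + s,
      roc_sweep(data, rand_seg, grid = seq(0.1, 0.9, by = 0.1),
                partial_chain = FALSE)$auc)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("nested sweeps give a monotone ROC and grid-stable AUC", {
  data <- tiny_dataset(n = 3, seed = 101)
  roc <- roc_sweep(data, ratio_segmenter(), ratio_threshold_grid(n = 30),
                   partial_chain = FALSE)
  pts <- dplyr::arrange(tidy(roc), 1 - specificity)
  expect_true(all(diff(pts$sensitivity) >= -1e-12))

  coarse <- roc_sweep(data, ratio_segmenter(),
                      ratio_threshold_grid(n = 50), partial_chain = FALSE)
  fine <- roc_sweep(data, ratio_segmenter(),
                    ratio_threshold_grid(n = 500), partial_chain = FALSE)
  expect_lt(abs(coarse$auc - fine$auc), 0.01)

  expect_error(roc_sweep(data, ratio_segmenter(), numeric(0)), "empty")
  expect_error(roc_sweep(data[0, ], ratio_segmenter(), 1), "empty")
})

# independent two-way ANOVA decomposition via aov(), plus the F-based CI
icc_oracle <- function(x, conf_level = 0.95) {
  n <- nrow(x); k <- ncol(x)
  df <- data.frame(y = as.vector(x),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(aov(y ~ subject + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  r <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  alpha <- 1 - conf_level
  a <- k * r / (n * (1 - r)); b <- 1 + k * r * (n - 1) / (n * (1 - r))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- qf(1 - alpha / 2, n - 1, v); fu <- qf(1 - alpha / 2, v, n - 1)
  c(r,
    n * (msr - fl * mse) / (fl * (k * msc + (k * n - k - n) * mse) + n * msr),
    n * (fu * msr - mse) / (k * msc + (k * n - k - n) * mse + n * fu * msr))
}

test_that("ICC(A,1) and its CI match the ANOVA oracle on random matrices", {
  withr::local_seed(103)
  for (i in 1:100) {
    n <- sample(5:12, 1); k <- sample(2:5, 1)
    x <- matrix(rnorm(n * k, mean = 100, sd = 20), n, k) +
      rnorm(n, sd = 30)  # subject effect recycled down columns
    got <- icc_absolute_agreement(x)
    want <- icc_oracle(x)
    expect_equal(got$icc, want[1], tolerance = 1e-10)
    expect_equal(unname(got$ci), want[2:3], tolerance = 1e-10)
  }
})

test_that("ICC rewards identity and punishes constant offsets", {
  withr::local_seed(107)
  subj <- rnorm(10, 100, 40)
  same <- cbind(subj, subj)
  expect_equal(icc_absolute_agreement(same)$icc, 1, tolerance = 1e-12)

  tight <- rnorm(12, 100, 1)
  offset <- cbind(tight, tight + 50)  # offset dwarfs subject variance
  expect_lt(icc_absolute_agreement(offset)$icc, 0.2)

  expect_error(icc_absolute_agreement(matrix(5, 6, 3)), "degenerate")
  expect_error(icc_absolute_agreement(matrix(1:8, 4, 2)), "at least 5")
})

test_that("Bland-Altman percent differences follow the pair-mean convention", {
  v <- c(50, 120, 800, 43, 9)
  same <- bland_altman(v, v)
  expect_equal(same$mean_diff, 0)
  expect_equal(unname(same$loa), c(0, 0))

  prop <- bland_altman(1.1 * v, v)
  expect_equal(prop$mean_diff, 0.1 / 1.05 * 100, tolerance = 1e-12)
  expect_equal(prop$sd_diff, 0, tolerance = 1e-12)

  withr::local_seed(109)
  a <- runif(30, 10, 1000); b <- runif(30, 10, 1000)
  got <- bland_altman(a, b)
  d <- (a - b) / ((a + b) / 2) * 100
  expect_equal(got$mean_diff, mean(d), tolerance = 1e-12)
  expect_equal(unname(got$loa),
               mean(d) + c(-1.96, 1.96) * sd(d), tolerance = 1e-12)

  expect_warning(z <- bland_altman(c(0, 5), c(0, 5)), "zero mean")
  expect_equal(nrow(tidy(z)), 1)
  expect_error(bland_altman(1:3, 1:4), "paired")
})

test_that("pooled confusion counts are additive across images", {
  withr::local_seed(113)
  preds <- lapply(1:4, function(i) random_mask(12, 12, 0.4))
  truths <- lapply(1:4, function(i) random_mask(12, 12, 0.4))
  per <- purrr::map2(preds, truths, confusion)
  pooled <- dplyr::bind_rows(per)
  expect_equal(sum(pooled$tp), sum(vapply(per, function(x) x$tp, numeric(1))))
  ss_pool <- sensitivity_specificity(pooled)
  tp <- sum(pooled$tp); fn <- sum(pooled$fn)
  expect_equal(ss_pool[["sensitivity"]], tp / (tp + fn))
})
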