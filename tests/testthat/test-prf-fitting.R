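test_that("predicted drive is normalized Gaussian-aperture overlap", {
  # tiny manual grid: one full-field frame, then an empty frame
  ax <- seq(-4.75, 4.75, by = 0.5)
  x <- rep(ax, times = length(ax)); y <- rep(ax, each = length(ax))
  masks <- rbind(rep(1, length(x)), rep(0, length(x)))
  ap <- manual_apertures(masks, x, y)
  delta_hrf <- structure(1, class = "hrf")
  p <- predict_timecourse(list(x = 0, y = 0, sigma = 1), ap, delta_hrf)
  expect_equal(p, c(1, 0))  # full field: overlap 1; baseline: 0
  # pRF far outside the field with tiny sigma drives nothing
  p_out <- predict_timecourse(list(x = 30, y = 30, sigma = 0.2), ap,
                              delta_hrf)
  expect_equal(p_out, c(0, 0))
  expect_error(predict_timecourse(list(x = 0, y = 0, sigma = -1), ap),
               "sigma")
})

test_that("baseline-only sequences predict a flat response", {
  ap <- test_apertures()
  base_only <- manual_apertures(ap$masks[ap$frame_table$baseline, ],
                                ap$x, ap$y)
  p <- predict_timecourse(list(x = 0, y = 0, sigma = 1), base_only)
  expect_true(all(p == 0))
})

test_that("surface smoothing preserves constants and reduces to identity", {
  gt <- make_ground_truth(60, seed = 3)
  g <- gt$graph
  v <- rep(2.5, 60)
  expect_equal(surface_smooth(v, g, 5), v)
  r <- rnorm(60)
  expect_identical(surface_smooth(r, g, 0), r)
})

test_that("impulse smoothing on a line graph matches the Gaussian kernel", {
  n <- 9
  verts <- data.frame(vertex = 1:n, hemi = "L", region = "V1",
                      x_mm = (0:(n - 1)) * 1.0, y_mm = 0)
  g <- cortical_sheet(verts, cbind(1:(n - 1), 2:n))
  imp <- c(rep(0, 4), 1, rep(0, 4))
  fwhm <- 2.355  # kernel SD exactly 1 mm
  sm <- surface_smooth(imp, g, fwhm)
  d <- abs((1:n) - 5)
  w <- exp(-d^2 / 2); w[d > 3] <- 0
  expect_equal(sm[5], w[5] / sum(exp(-((-3):3)^2 / 2)), tolerance = 1e-12)
  expect_equal(sm, as.numeric(sapply(1:n, function(i) {
    wi <- exp(-abs((1:n) - i)^2 / 2); wi[abs((1:n) - i) > 3] <- 0
    sum(wi * imp) / sum(wi)
  })), tolerance = 1e-12)
})

test_that("coarse fit matches an independent brute-force grid search", {
  ap <- test_apertures()
  hrf <- hrf_double_gamma()
  grid <- expand.grid(x = seq(-4, 4, length.out = 5),
                      y = seq(-4, 4, length.out = 5),
                      sigma = c(0.5, 1, 2))
  design <- prf_design(ap, hrf, grid)
  set.seed(42)
  y <- predict_timecourse(list(x = grid$x[33], y = grid$y[33],
                               sigma = grid$sigma[33]), ap, hrf) +
    rnorm(348, 0, 0.01)
  got <- coarse_fit(y, design)
  # oracle: explicit loop over the grid computing Pearson correlations
  r_loop <- vapply(seq_len(nrow(grid)), function(k) {
    p <- predict_timecourse(list(x = grid$x[k], y = grid$y[k],
                                 sigma = grid$sigma[k]), ap, hrf)
    if (sd(p) < 1e-10) 0 else cor(y, p)
  }, numeric(1))
  expect_equal(got$grid_index, which.max(r_loop))
  expect_equal(got$r2, max(r_loop)^2, tolerance = 1e-10)
})

test_that("noiseless grid vertices are recovered exactly by the coarse fit", {
  design <- test_design()
  k <- 321
  y <- design$predictions[, k]
  got <- coarse_fit(y, design)
  expect_equal(got$grid_index, k)
  expect_equal(got$r2, 1, tolerance = 1e-10)
})

test_that("zero-variance series are flagged unfit", {
  got <- coarse_fit(rep(1, 348), test_design())
  expect_true(is.na(got$r2))
})

test_that("fine fit recovers off-grid truth from noiseless data", {
  design <- test_design()
  ap <- test_apertures()
  truth <- list(x = 2.3, y = -1.1, sigma = 1.7)
  y <- predict_timecourse(truth, ap, design$hrf)
  start <- coarse_fit(y, design)
  expect_gt(start$r2, 0.05)
  fit <- fine_fit(y, design, start, maxit = 600)
  expect_lt(abs(fit$x - truth$x), 0.05)
  expect_lt(abs(fit$y - truth$y), 0.05)
  expect_lt(abs(fit$sigma - truth$sigma), 0.05)
  expect_gt(fit$r2, 0.999)
})

test_that("fine fit never increases the residual sum of squares", {
  design <- test_design()
  ap <- test_apertures()
  set.seed(9)
  for (i in 1:3) {
    truth <- list(x = runif(1, -4, 4), y = runif(1, -4, 4),
                  sigma = runif(1, 0.5, 2))
    y <- predict_timecourse(truth, ap, design$hrf)
    y <- y / max(abs(y)) + rnorm(348, 0, 0.5)  # low SNR on purpose
    start <- coarse_fit(y, design)
    fit <- fine_fit(y, design, start, maxit = 150)
    m0 <- predict_timecourse(start, ap, design$hrf)
    b <- cov(m0, y) / var(m0)
    rss_start <- sum((b * m0 + (mean(y) - b * mean(m0)) - y)^2)
    expect_lte(fit$rss, rss_start + 1e-9)
    expect_gt(fit$sigma, 0)
  }
})

test_that("r2 thresholding reports retention and handles the extremes", {
  map <- data.frame(vertex = 1:10, r2 = c(seq(0, 0.9, 0.1)))
  all_kept <- threshold_by_r2(map, 0)
  expect_equal(nrow(all_kept), 9)  # r2 must exceed the threshold
  expect_error(threshold_by_r2(map, 1), "r2_min")
  half <- threshold_by_r2(map, 0.45)
  expect_equal(attr(half, "retention"), 0.5)
})

test_that("r2 threshold p-values reproduce the printed correspondences", {
  expect_equal(signif(r2_threshold_pvalue(0.03, 348), 2), 0.0012)
  expect_equal(signif(r2_threshold_pvalue(0.05, 348), 1), 3e-5)
  expect_gt(r2_threshold_pvalue(1e-8, 348), 0.99)
  expect_error(r2_threshold_pvalue(0.03, 2), "samples")
})
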