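test_that("orthogonal regression recovers exact lines", {
  theta <- seq(-150, 150, by = 10)
  fit1 <- orthogonal_regression(theta, theta)
  expect_equal(fit1$slope, 1, tolerance = 1e-12)
  expect_equal(fit1$intercept, 0, tolerance = 1e-10)
  fit2 <- orthogonal_regression(theta / 2, theta + 10)
  expect_equal(fit2$slope, 2, tolerance = 1e-12)
  expect_equal(fit2$intercept, 10, tolerance = 1e-10)
  expect_error(orthogonal_regression(rep(1, 5), rep(2, 5)), "variance")
  expect_error(orthogonal_regression(1:2, 1:2), "at least 3")
})

test_that("total least squares resists the attenuation that biases OLS", {
  set.seed(21)
  t_true <- runif(400, -120, 120)
  theta <- t_true + rnorm(400, 0, 20)
  phi <- t_true + rnorm(400, 0, 20)
  tls <- orthogonal_regression(theta, phi)$slope
  ols <- coef(lm(phi ~ theta))[2]
  expect_lt(abs(tls - 1), 0.08)
  expect_lt(ols, 0.96)  # OLS attenuates towards zero
  expect_lt(abs(tls - 1), abs(ols - 1))
})

test_that("identity Akaike weight separates matched from independent angles", {
  set.seed(5)
  theta <- runif(500, -180, 180)
  w_match <- aic_weight_identity(theta, theta + rnorm(500, 0, 5))
  expect_gt(as.numeric(w_match), 0.999)
  # three weights are a simplex
  expect_equal(sum(attr(w_match, "weights")), 1, tolerance = 1e-12)
  # independent angles: evidence for the identity model collapses
  hits <- vapply(1:20, function(i) {
    set.seed(100 + i)
    th <- runif(500, -180, 180)
    ph <- runif(500, -180, 180)
    as.numeric(aic_weight_identity(th, ph)) < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("wrapped and circular-mean AIC variants are available and coherent", {
  set.seed(6)
  theta <- runif(100, -180, 180)
  phi <- wrap_angle_deg(theta + rnorm(100, 0, 5))
  for (w in list(aic_weight_identity(theta, phi, wrap = TRUE),
                 aic_weight_identity(theta, phi, wrap = TRUE,
                                     level = "circular_mean"))) {
    expect_gt(as.numeric(w), 0.99)
    expect_equal(sum(attr(w, "weights")), 1, tolerance = 1e-12)
  }
})

test_that("the fitted level of the constant models minimizes wrapped RSS", {
  set.seed(55)
  for (i in 1:10) {
    # mixture samples put the circular mean far from the RSS minimizer
    a <- wrap_angle_deg(c(rnorm(8, runif(1, -180, 180), 10),
                          rnorm(5, runif(1, -180, 180), 10)))
    opt <- retinomap:::wrapped_rss_level(a)
    grid <- seq(-179.99, 180, by = 0.02)
    rss_grid <- vapply(grid, function(c0) sum(wrap_angle_deg(a - c0)^2),
                       numeric(1))
    expect_lte(opt$rss, min(rss_grid) + 1e-8)
    cm <- retinomap:::circular_mean_deg(a)
    expect_lte(opt$rss, sum(wrap_angle_deg(a - cm)^2) + 1e-8)
  }
})

test_that("Fisher-Lee correlation matches its brute-force double loop", {
  brute <- function(theta, phi) {
    t_r <- theta * pi / 180; p_r <- phi * pi / 180
    n <- length(theta)
    num <- 0; dt <- 0; dp <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        num <- num + sin(t_r[i] - t_r[j]) * sin(p_r[i] - p_r[j])
        dt <- dt + sin(t_r[i] - t_r[j])^2
        dp <- dp + sin(p_r[i] - p_r[j])^2
      }
    }
    num / sqrt(dt * dp)
  }
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(4:9, 1)
    theta <- runif(n, -180, 180)
    phi <- runif(n, -180, 180)
    expect_equal(fisher_lee_correlation(theta, phi), brute(theta, phi),
                 tolerance = 1e-12)
  }
  theta <- runif(30, -180, 180)
  expect_equal(fisher_lee_correlation(theta, theta), 1, tolerance = 1e-12)
  expect_equal(fisher_lee_correlation(theta, -theta), -1, tolerance = 1e-12)
})

test_that("Fisher-Lee correlation is rotation invariant", {
  set.seed(13)
  theta <- runif(40, -180, 180)
  phi <- theta + rnorm(40, 0, 30)
  base <- fisher_lee_correlation(theta, phi)
  for (rot in c(45, -120, 200)) {
    rotated <- fisher_lee_correlation(wrap_angle_deg(theta + rot),
                                      wrap_angle_deg(phi - 2 * rot))
    expect_equal(rotated, base, tolerance = 1e-12)
  }
})

test_that("degenerate angular spreads are flagged", {
  expect_warning(out <- fisher_lee_correlation(rep(10, 5), runif(5, -180, 180)),
                 "degenerate")
  expect_true(is.na(out))
})

test_that("permutation test is calibrated, seeded and exact for identity", {
  theta <- seq(-179, 180, length.out = 200)
  res <- permutation_test_cc(theta, theta, n_perm = 999, seed = 2)
  expect_equal(res$p, 1 / 1000)
  res2 <- permutation_test_cc(theta, theta, n_perm = 999, seed = 2)
  expect_identical(res, res2)
  # null calibration: p approximately uniform
  set.seed(31)
  p_null <- vapply(1:60, function(i) {
    th <- runif(40, -180, 180)
    ph <- runif(40, -180, 180)
    permutation_test_cc(th, ph, n_perm = 199, seed = i)$p
  }, numeric(1))
  expect_lt(abs(mean(p_null < 0.5) - 0.5), 0.2)
  expect_lte(mean(p_null < 0.05), 0.15)
})

test_that("normative envelope has calibrated coverage and classifies extremes", {
  set.seed(77)
  # correlated bivariate normal controls
  ch <- chol(matrix(c(0.04, 0.01, 0.01, 25), 2))
  draw <- function(n) {
    z <- matrix(rnorm(2 * n), n) %*% ch
    data.frame(slope = 1 + z[, 1], intercept = z[, 2],
               cc_fl = runif(n, 0.3, 0.9))
  }
  controls <- draw(10000)
  env <- normative_range(controls)
  held_out <- draw(10000)
  inside <- vapply(seq_len(nrow(held_out)), function(i) {
    isTRUE(classify_against_envelope(env, held_out[i, ])$inside_ellipse)
  }, logical(1))
  expect_lt(abs(mean(inside) - 0.95), 0.03)
  # the mean point is inside; a 10-Mahalanobis-unit point is outside
  centre <- data.frame(slope = env$mean[1], intercept = env$mean[2],
                       cc_fl = 0.6)
  expect_true(classify_against_envelope(env, centre)$inside_ellipse)
  far <- data.frame(slope = env$mean[1] + 10 * sqrt(env$cov[1, 1]),
                    intercept = env$mean[2], cc_fl = 0.6)
  expect_false(classify_against_envelope(env, far)$inside_ellipse)
  expect_error(normative_range(controls[1:2, ]), "at least 3")
})

test_that("linear correspondence mirrors the angular analysis for x/y/ecc", {
  set.seed(3)
  rod <- runif(200, 0.5, 8.5)
  cone <- rod + rnorm(200, 0, 0.3)
  res <- linear_correspondence(rod, cone)
  expect_gt(res$aic_w, 0.99)
  expect_gt(res$cor, 0.95)
  expect_equal(res$slope, 1, tolerance = 0.1)
})
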