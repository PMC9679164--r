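test_that("excitation matrix equals pointwise products for delta-like primaries", {
  grid <- default_wavelength_grid()
  delta_spd <- function(peak) {
    v <- numeric(length(grid))
    v[grid == peak] <- 1
    spectral_curve(grid, v)
  }
  disp <- display_model(red = delta_spd(610), green = delta_spd(530),
                        blue = delta_spd(450))
  rec <- toy_receptors()
  m <- build_excitation_matrix(disp, rec)
  # delta SPD x sensitivity x 1 nm step: entry is the fundamental at the peak
  for (r in c("L", "M", "S", "rod")) {
    sens <- resample_spectrum(rec[[r]], grid)$value
    expect_equal(m[r, "R"], sens[grid == 610], tolerance = 1e-12)
    expect_equal(m[r, "G"], sens[grid == 530], tolerance = 1e-12)
    expect_equal(m[r, "B"], sens[grid == 450], tolerance = 1e-12)
  }
})

test_that("excitation matrix is linear in the SPDs and zero for dark primaries", {
  grid <- default_wavelength_grid()
  zero <- spectral_curve(grid, numeric(length(grid)))
  rec <- toy_receptors()
  m0 <- build_excitation_matrix(display_model(zero, zero, zero), rec)
  expect_true(all(m0 == 0))
  d1 <- synthetic_display_model()
  double <- function(cv) spectral_curve(cv$wavelength_nm, 2 * cv$value)
  d2 <- display_model(double(d1$primary_spds$R), double(d1$primary_spds$G),
                      double(d1$primary_spds$B))
  expect_equal(build_excitation_matrix(d2, rec),
               2 * build_excitation_matrix(d1, rec), tolerance = 1e-12)
})

test_that("excitation matrix is stable under wavelength-grid refinement", {
  d <- toy_display(); rec <- toy_receptors()
  m1 <- build_excitation_matrix(d, rec, grid_nm = seq(390, 780, by = 1))
  m2 <- build_excitation_matrix(d, rec, grid_nm = seq(390, 780, by = 0.5))
  expect_lt(max(abs(m1 - m2) / m1), 0.001)  # Riemann-sum convergence
})

test_that("receptor excitations follow the gamma-linearized matrix product", {
  d <- toy_display(gamma = 2.2)
  rec <- toy_receptors()
  m <- toy_matrix(2.2)
  expect_equal(unname(receptor_excitation(d, rec, c(0, 0, 0), m)), rep(0, 4))
  expect_equal(receptor_excitation(toy_display(1), rec, c(1, 0, 0),
                                   toy_matrix(1)), m[, "R"])
  expect_equal(receptor_excitation(d, rec, rep(0.5, 3), m),
               drop(m %*% rep(0.5^2.2, 3)))
  expect_error(receptor_excitation(d, rec, c(1.2, 0, 0), m), "0, 1")
})

test_that("michelson contrast follows its definition", {
  expect_equal(michelson_contrast(2, 1), 1 / 3)
  expect_equal(michelson_contrast(3, 1), 0.5)
  expect_equal(michelson_contrast(5, 5), 0)
  expect_error(michelson_contrast(0, 0), "zero")
  expect_error(michelson_contrast(-1, 1), "non-negative")
})

test_that("cone-isolating pairs silence rods and hit the requested L/M contrast", {
  d <- toy_display(gamma = 2.2)
  rec <- toy_receptors()
  m <- toy_matrix(2.2)
  pair <- solve_cone_isolating_pair(d, rec, target_lm_contrast = 0.2,
                                    matrix = m)
  ct <- pair_contrasts(pair, d, rec, m)
  expect_lt(abs(ct[["rod"]]), 1e-9)
  expect_equal(mean(abs(ct[c("L", "M")])), 0.2, tolerance = 1e-6)
  expect_identical(pair$background_drive[3], pair$target_drive[3])
  # stored contrasts are recomputable from the drives
  expect_equal(unname(ct), unname(pair$receptor_contrasts), tolerance = 1e-9)
  # zero request returns the background unchanged
  p0 <- solve_cone_isolating_pair(d, rec, target_lm_contrast = 0, matrix = m)
  expect_identical(p0$background_drive, p0$target_drive)
  expect_true(all(p0$receptor_contrasts == 0))
})

test_that("cone-isolating solve matches the closed-form toy system", {
  # rod row (1,1): null direction proportional to (1,-1) in the R-G plane
  m <- rbind(L = c(2, 1, 0.2), M = c(1, 2, 0.2),
             S = c(0.1, 0.1, 1), rod = c(1, 1, 0.5))
  colnames(m) <- c("R", "G", "B")
  d <- toy_display(gamma = 1)
  rec <- toy_receptors()
  pair <- solve_cone_isolating_pair(d, rec, rep(0.5, 3), 0.1, matrix = m)
  delta <- pair$target_drive - pair$background_drive
  expect_equal(delta[1], -delta[2], tolerance = 1e-10)
  expect_equal(delta[3], 0)
  # closed-form mean L/M contrast along (1,-1)/sqrt(2) with symmetric rows
  e <- drop(m %*% rep(0.5, 3))
  s <- delta[1] * sqrt(2)
  k <- s / sqrt(2)
  mean_lm <- (k / (2 * e[["L"]] + k) + k / (2 * e[["M"]] - k)) / 2
  expect_equal(mean_lm, 0.1, tolerance = 1e-6)
})

test_that("contrast scaling is near-linear in the drive deltas before clipping", {
  d <- toy_display(gamma = 1)
  rec <- toy_receptors()
  m <- toy_matrix(1)
  d1 <- solve_cone_isolating_pair(d, rec, target_lm_contrast = 0.002,
                                  matrix = m)
  d2 <- solve_cone_isolating_pair(d, rec, target_lm_contrast = 0.004,
                                  matrix = m)
  delta1 <- d1$target_drive - d1$background_drive
  delta2 <- d2$target_drive - d2$background_drive
  # both modulations lie on the same rod-null direction...
  expect_equal(delta2 / sqrt(sum(delta2^2)), delta1 / sqrt(sum(delta1^2)),
               tolerance = 1e-9)
  # ...and the step is proportional to the requested (small) contrast, up
  # to the O(c) curvature of the Michelson denominator
  expect_equal(delta2, 2 * delta1, tolerance = 5e-3)
})

test_that("gamut violations fail loudly and name the limiting channel", {
  d <- toy_display(gamma = 1)
  rec <- toy_receptors()
  expect_error(solve_cone_isolating_pair(d, rec, rep(0.5, 3), 5,
                                         matrix = toy_matrix(1)),
               "gamut")
})

test_that("rod-isolating pairs silence both cone classes", {
  d <- toy_display(gamma = 2.2)
  rec <- toy_receptors()
  m <- toy_matrix(2.2)
  pair <- solve_rod_isolating_pair(d, rec, target_rod_contrast = 0.1,
                                   matrix = m)
  ct <- pair_contrasts(pair, d, rec, m)
  expect_lt(abs(ct[["L"]]), 1e-9)
  expect_lt(abs(ct[["M"]]), 1e-9)
  expect_equal(abs(ct[["rod"]]), 0.1, tolerance = 1e-6)
  expect_equal(unname(ct), unname(pair$receptor_contrasts), tolerance = 1e-9)
  p0 <- solve_rod_isolating_pair(d, rec, target_rod_contrast = 0, matrix = m)
  expect_identical(p0$background_drive, p0$target_drive)
})

test_that("rod-isolating direction matches an explicit null-space computation", {
  m <- rbind(L = c(1, 0, 0), M = c(0, 1, 0),
             S = c(0.2, 0.2, 1), rod = c(0.3, 0.5, 0.8))
  colnames(m) <- c("R", "G", "B")
  pair <- solve_rod_isolating_pair(toy_display(1), toy_receptors(),
                                   rep(0.5, 3), 0.05, matrix = m)
  delta <- pair$target_drive - pair$background_drive
  # null space of rows L=(1,0,0), M=(0,1,0) is the B axis
  expect_equal(delta[1], 0, tolerance = 1e-12)
  expect_equal(delta[2], 0, tolerance = 1e-12)
  expect_gt(delta[3], 0)
})

test_that("validate_pair reports residuals under perturbed display spectra", {
  d <- toy_display(gamma = 1)
  rec <- toy_receptors()
  pair <- solve_cone_isolating_pair(d, rec, target_lm_contrast = 0.05,
                                    matrix = toy_matrix(1))
  ok <- validate_pair(pair, d, rec, silenced = "rod", tol = 1e-6)
  expect_true(ok$pass)
  expect_lt(ok$residuals[["rod"]], 1e-9)
  # simulated measurement error: shift the green primary by 3 nm
  g <- d$primary_spds$G
  d_bad <- display_model(d$primary_spds$R,
                         spectral_curve(g$wavelength_nm + 3, g$value),
                         d$primary_spds$B)
  bad <- validate_pair(pair, d_bad, rec, silenced = "rod", tol = 1e-6)
  expect_false(bad$pass)
  expect_gt(bad$residuals[["rod"]], 1e-6)
  # empty silenced list passes vacuously
  expect_true(validate_pair(pair, d_bad, rec, silenced = character(0))$pass)
})

test_that("spectral curves round-trip through delimited text", {
  cv <- photopigment_template(520)
  path <- tempfile(fileext = ".txt")
  write_spectral_curve(cv, path)
  back <- read_spectral_curve(path)
  expect_equal(back$wavelength_nm, cv$wavelength_nm)
  expect_equal(back$value, cv$value, tolerance = 1e-12)
})

test_that("shipped synthetic fundamentals load as a valid receptor set", {
  rec <- load_synthetic_fundamentals()
  expect_s3_class(rec, "receptor_set")
  for (r in c("L", "M", "S", "rod")) expect_equal(max(rec[[r]]$value), 1)
})
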