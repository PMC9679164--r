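#' pRF parameter set
#'
#' @param x,y Preferred visual-field position (deg).
#' @param sigma pRF size (deg, SD of the symmetric bivariate Gaussian; > 0).
#' @param amplitude Response scale (arbitrary units).
#' @param baseline Additive offset.
#' @param r_squared Goodness of fit in [0, 1] (squared Pearson correlation).
#' @return A list of class `prf_parameters` with derived `eccentricity`
#'   (`sqrt(x^2 + y^2)`) and `polar_angle` (`atan2(y, x)` in degrees,
#'   0 = right horizontal meridian, anticlockwise positive, (-180, 180]).
#' @export
prf_parameters <- function(x, y, sigma, amplitude = 1, baseline = 0,
                           r_squared = NA_real_) {
  if (!is.na(sigma) && sigma <= 0) stop("sigma must be positive")
  structure(list(x = x, y = y, sigma = sigma, amplitude = amplitude,
                 baseline = baseline, r_squared = r_squared,
                 eccentricity = sqrt(x^2 + y^2),
                 polar_angle = wrap_angle_deg(atan2(y, x) * 180 / pi)),
            class = "prf_parameters")
}

# normalized Gaussian overlap drive of one pRF with every aperture frame:
# drive_t = sum_px G(px) * mask_t(px) / sum_px G(px)
prf_drive <- function(x, y, sigma, apertures) {
  g <- exp(-((apertures$x - x)^2 + (apertures$y - y)^2) / (2 * sigma^2))
  s <- sum(g)
  if (s < 1e-12) return(numeric(nrow(apertures$masks)))
  m <- if (is.null(apertures$masks_sparse)) apertures$masks else
    apertures$masks_sparse
  as.numeric(m %*% g) / s
}

#' Predict a BOLD time course from a Gaussian pRF
#'
#' Neural drive per frame is the overlap of the peak-normalized Gaussian
#' receptive field with the binary aperture, normalized by the Gaussian's
#' total mass on the grid; the drive is convolved with the HRF and truncated
#' to the run length.
#'
#' @param params A [prf_parameters()] (or any list with `x`, `y`, `sigma`,
#'   optionally `amplitude` and `baseline`).
#' @param apertures An [compose_run()] aperture sequence.
#' @param hrf An [hrf_double_gamma()] kernel.
#' @return Numeric predicted series of length `nrow(apertures$masks)`.
#' @export
predict_timecourse <- function(params, apertures, hrf = hrf_double_gamma()) {
  if (is.null(params$sigma) || params$sigma <= 0) {
    stop("sigma must be positive")
  }
  amp <- if (is.null(params$amplitude)) 1 else params$amplitude
  base <- if (is.null(params$baseline)) 0 else params$baseline
  drive <- prf_drive(params$x, params$y, params$sigma, apertures)
  amp * convolve_hrf(drive, hrf) + base
}

#' Default coarse-fit search grid
#'
#' Polar position grid (log-spaced eccentricities crossed with angles, plus
#' the origin) covering the field slightly beyond the stimulated extent, and
#' log-spaced pRF sizes.
#'
#' @param n_ecc,n_angle,n_sigma Grid resolution per dimension.
#' @param ecc_range Eccentricity range (deg).
#' @param sigma_range pRF size range (deg).
#' @return Data frame with columns `x`, `y`, `sigma`.
#' @export
default_prf_grid <- function(n_ecc = 12, n_angle = 24, n_sigma = 8,
                             ecc_range = c(0.3, 9),
                             sigma_range = c(0.18, 9)) {
  ecc <- exp(seq(log(ecc_range[1]), log(ecc_range[2]), length.out = n_ecc))
  ang <- seq(0, 360, length.out = n_angle + 1)[-(n_angle + 1)] * pi / 180
  pos <- rbind(data.frame(x = 0, y = 0),
               expand.grid(e = ecc, a = ang) |>
                 (\(d) data.frame(x = d$e * cos(d$a), y = d$e * sin(d$a)))())
  sig <- exp(seq(log(sigma_range[1]), log(sigma_range[2]),
                 length.out = n_sigma))
  out <- merge(pos, data.frame(sigma = sig))
  out[, c("x", "y", "sigma")]
}

# FFT-based causal convolution of every column with the HRF
convolve_columns <- function(mat, hrf) {
  n <- nrow(mat)
  nf <- n + length(hrf) - 1L
  pad <- rbind(mat, matrix(0, nf - n, ncol(mat)))
  hf <- stats::fft(c(hrf, rep(0, nf - length(hrf))))
  out <- Re(stats::mvfft(stats::mvfft(pad) * hf, inverse = TRUE)) / nf
  out[seq_len(n), , drop = FALSE]
}

#' Precompute the grid-search design for pRF fitting
#'
#' Renders every grid pRF's predicted time course once, so coarse fits over
#' many vertices reduce to one correlation matrix product.
#'
#' @param apertures An [compose_run()] aperture sequence.
#' @param hrf HRF kernel.
#' @param grid Search grid from [default_prf_grid()].
#' @return An object of class `prf_design` holding the apertures, HRF, grid
#'   and the T x K prediction matrix (raw and standardized).
#' @export
prf_design <- function(apertures, hrf = hrf_double_gamma(),
                       grid = default_prf_grid()) {
  stopifnot(nrow(grid) > 0)
  gx <- apertures$x; gy <- apertures$y
  n_px <- length(gx)
  gauss <- matrix(0, n_px, nrow(grid))
  for (k in seq_len(nrow(grid))) {
    gauss[, k] <- exp(-((gx - grid$x[k])^2 + (gy - grid$y[k])^2) /
                        (2 * grid$sigma[k]^2))
  }
  mass <- colSums(gauss)
  drive <- apertures$masks %*% gauss
  ok <- mass > 1e-12
  drive[, ok] <- sweep(drive[, ok, drop = FALSE], 2, mass[ok], `/`)
  drive[, !ok] <- 0
  pred <- convolve_columns(drive, hrf)
  cs <- scale(pred, center = TRUE, scale = FALSE)
  nrm <- sqrt(colSums(cs^2))
  degenerate <- nrm < 1e-10
  nrm[degenerate] <- 1
  structure(list(apertures = apertures, hrf = hrf, grid = grid,
                 predictions = pred,
                 predictions_std = sweep(cs, 2, nrm, `/`),
                 degenerate = degenerate),
            class = "prf_design")
}

# correlation of each standardized series column with each grid prediction
coarse_correlations <- function(y_mat, design) {
  ys <- scale(y_mat, center = TRUE, scale = FALSE)
  nrm <- sqrt(colSums(ys^2))
  flat <- nrm < 1e-10
  nrm[flat] <- 1
  ys <- sweep(ys, 2, nrm, `/`)
  r <- crossprod(ys, design$predictions_std)  # V x K
  r[, design$degenerate] <- 0
  r[flat, ] <- NA_real_
  r
}

#' Coarse (grid-search) pRF fit
#'
#' Exhaustive search over the design grid for the parameters maximizing the
#' Pearson correlation between the (typically surface-smoothed) series and
#' the grid predictions. Ties are broken by the first grid index.
#'
#' @param ts Numeric time series (one vertex) or a T x V matrix.
#' @param design A [prf_design()].
#' @return One-row (or V-row) data frame: `x`, `y`, `sigma`, `r2`, `grid_index`.
#'   Zero-variance series yield `NA` parameters (flagged unfit).
#' @export
coarse_fit <- function(ts, design) {
  y <- if (is.matrix(ts)) ts else matrix(ts, ncol = 1)
  r <- coarse_correlations(y, design)
  best <- apply(r, 1, function(z) if (all(is.na(z))) NA_integer_ else
    which.max(z))
  out <- data.frame(x = design$grid$x[best], y = design$grid$y[best],
                    sigma = design$grid$sigma[best],
                    r2 = r[cbind(seq_len(nrow(r)), best)]^2,
                    grid_index = best)
  out
}

#' Fine (simplex) pRF fit
#'
#' Derivative-free Nelder-Mead refinement minimizing the residual sum of
#' squares over (x, y, sigma, amplitude, baseline) against the unsmoothed
#' series. The two linear parameters are profiled out: for every candidate
#' (x, y, sigma) the exact least-squares amplitude and baseline are
#' substituted, so the simplex searches only the three shape parameters of
#' the same objective — the optimum is unchanged and the search is far
#' better conditioned. Sigma is optimized on the log scale so the fit can
#' never return a non-positive size; the simplex restarts once if it
#' exhausts its iteration budget. The reported `r2` is the squared Pearson
#' correlation between the fitted model and the data; the descent property
#' RSS(fit) <= RSS(start) always holds (on non-convergence the start is
#' returned with `converged = FALSE`).
#'
#' @param ts Numeric time series (one vertex).
#' @param design A [prf_design()] (provides apertures + HRF).
#' @param start Starting parameters (a row of [coarse_fit()] output or a
#'   list with `x`, `y`, `sigma`).
#' @param maxit Maximum simplex iterations (per start).
#' @return A one-row data frame: `x`, `y`, `sigma`, `amplitude`, `baseline`,
#'   `r2`, `rss`, `converged`.
#' @export
fine_fit <- function(ts, design, start, maxit = 500) {
  apertures <- design$apertures
  hrf <- design$hrf
  t_n <- length(ts)
  ts_mean <- mean(ts)
  ts_ss <- sum((ts - ts_mean)^2)
  model_for <- function(x, y, sigma) {
    convolve_hrf(prf_drive(x, y, sigma, apertures), hrf)
  }
  # profiled objective: exact LS amplitude/baseline for the candidate shape
  profile_fit <- function(m) {
    mm <- mean(m)
    sxx <- sum((m - mm)^2)
    if (!is.finite(sxx) || sxx < 1e-14) {
      return(c(amplitude = 0, baseline = ts_mean, rss = ts_ss))
    }
    b <- sum((m - mm) * (ts - ts_mean)) / sxx
    c(amplitude = b, baseline = ts_mean - b * mm,
      rss = ts_ss - b^2 * sxx)
  }
  rss_of <- function(p) profile_fit(model_for(p[1], p[2], exp(p[3])))[["rss"]]
  p0 <- c(start$x, start$y, log(start$sigma))
  rss0 <- rss_of(p0)
  opt <- stats::optim(p0, rss_of, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-7))
  if (opt$convergence != 0L) {
    # restart once with a fresh simplex; rescues slow high-eccentricity fits
    opt <- stats::optim(opt$par, rss_of, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-7))
  }
  converged <- opt$convergence == 0L
  p <- if (opt$value <= rss0) opt$par else p0
  m <- model_for(p[1], p[2], exp(p[3]))
  ab <- profile_fit(m)
  fitted <- ab[["amplitude"]] * m + ab[["baseline"]]
  r2 <- if (stats::sd(fitted) < 1e-12 || stats::sd(ts) < 1e-12) 0 else
    stats::cor(fitted, ts)^2
  data.frame(x = p[1], y = p[2], sigma = exp(p[3]),
             amplitude = ab[["amplitude"]], baseline = ab[["baseline"]],
             r2 = r2, rss = ab[["rss"]], converged = converged)
}

#' Smooth per-vertex values along the cortical surface
#'
#' Gaussian-weighted average over geodesic (graph) distances with kernel
#' SD = fwhm / 2.355, truncated at 3 SD. `fwhm = 0` is the identity; a
#' disconnected vertex is smoothed with itself only. `NA` entries are
#' excluded from every weighted average (and stay `NA` where the centre
#' value is `NA`).
#'
#' @param values Numeric vector (length V) or V x k matrix.
#' @param graph A [cortical_sheet()] graph.
#' @param fwhm_mm Kernel full-width at half-maximum (mm).
#' @return Smoothed values, same shape as the input.
#' @export
surface_smooth <- function(values, graph, fwhm_mm) {
  if (fwhm_mm < 0) stop("fwhm must be non-negative")
  if (fwhm_mm == 0) return(values)
  w <- smoothing_weights(graph, fwhm_mm)
  v <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  ok <- !is.na(v)
  v0 <- v
  v0[!ok] <- 0
  num <- w %*% v0
  den <- w %*% ok
  out <- num / den
  out[den == 0] <- NA
  out[!ok] <- NA
  if (is.matrix(values)) out else drop(out)
}

smoothing_weights <- function(graph, fwhm_mm) {
  sigma <- fwhm_mm / 2.355
  d <- graph_distances(graph)
  w <- exp(-d^2 / (2 * sigma^2))
  w[d > 3 * sigma] <- 0
  w[!is.finite(d)] <- 0
  diag(w) <- 1
  w
}

#' Exclude low goodness-of-fit vertices from a pRF map
#'
#' @param map Data frame of fitted pRF parameters with an `r2` column.
#' @param r2_min Exclusion threshold in [0, 1): vertices with
#'   `r2 <= r2_min` (or unfit `NA`) are removed.
#' @return The filtered map, with attribute `retention` giving the retained
#'   fraction.
#' @export
threshold_by_r2 <- function(map, r2_min = 0.03) {
  if (r2_min < 0 || r2_min >= 1) stop("r2_min must lie in [0, 1)")
  keep <- !is.na(map$r2) & map$r2 > r2_min
  out <- map[keep, , drop = FALSE]
  attr(out, "retention") <- mean(keep)
  out
}

#' Two-tailed p-value of an R-squared exclusion threshold
#'
#' The p-value of observing a squared Pearson correlation of `r2_min`
#' between a model prediction and `n_samples` data points under the null of
#' no correlation: `t = r sqrt(n - 2) / sqrt(1 - r^2)` referred to a t
#' distribution with `n - 2` degrees of freedom (two-tailed).
#'
#' @param r2_min Threshold in (0, 1).
#' @param n_samples Number of time points (> 2).
#' @return The two-tailed p-value.
#' @export
r2_threshold_pvalue <- function(r2_min, n_samples) {
  if (n_samples <= 2) stop("need more than 2 samples")
  if (r2_min <= 0 || r2_min >= 1) stop("r2_min must lie in (0, 1)")
  r <- sqrt(r2_min)
  t <- r * sqrt(n_samples - 2) / sqrt(1 - r2_min)
  2 * stats::pt(-t, df = n_samples - 2)
}

#' Fit a full pRF map with the two-stage coarse/fine procedure
#'
#' Surface-smooths the data (FWHM `fwhm_data_mm`), grid-searches every
#' vertex on the smoothed series, refines vertices whose coarse fit exceeds
#' `r2_fine` against the unsmoothed series with the simplex optimizer, then
#' smooths the fitted x, y and sigma along the surface (FWHM
#' `fwhm_params_mm`, across fitted vertices only) and derives eccentricity
#' and polar angle.
#'
#' @param ts_mat T x V matrix of vertex time series (TR-resolution samples).
#' @param design A [prf_design()].
#' @param graph A [cortical_sheet()] with V vertices.
#' @param fwhm_data_mm Data smoothing before the coarse stage (default 5).
#' @param fwhm_params_mm Parameter smoothing after fitting (default 3).
#' @param r2_fine Coarse-fit threshold for entering the fine stage
#'   (default 0.05).
#' @param fine Run the fine stage (default `TRUE`; `FALSE` keeps coarse
#'   estimates, with `r2` recomputed against the unsmoothed series).
#' @param maxit Simplex iteration cap per vertex.
#' @return Data frame (one row per vertex): `vertex`, `x`, `y`, `sigma`,
#'   `amplitude`, `baseline`, `r2`, `coarse_r2`, `fine`, `ecc`, `polar`.
#' @export
fit_prf_map <- function(ts_mat, design, graph, fwhm_data_mm = 5,
                        fwhm_params_mm = 3, r2_fine = 0.05, fine = TRUE,
                        maxit = 500) {
  v_n <- ncol(ts_mat)
  stopifnot(v_n == n_vertices(graph))
  smoothed <- t(surface_smooth(t(ts_mat), graph, fwhm_data_mm))
  coarse <- coarse_fit(smoothed, design)
  fit <- data.frame(vertex = seq_len(v_n), x = coarse$x, y = coarse$y,
                    sigma = coarse$sigma, amplitude = NA_real_,
                    baseline = NA_real_, r2 = NA_real_,
                    coarse_r2 = coarse$r2, fine = FALSE)
  for (v in seq_len(v_n)) {
    if (is.na(coarse$r2[v])) next
    y <- ts_mat[, v]
    if (fine && coarse$r2[v] > r2_fine) {
      ff <- fine_fit(y, design, coarse[v, ], maxit = maxit)
      fit$x[v] <- ff$x; fit$y[v] <- ff$y; fit$sigma[v] <- ff$sigma
      fit$amplitude[v] <- ff$amplitude; fit$baseline[v] <- ff$baseline
      fit$r2[v] <- ff$r2; fit$fine[v] <- TRUE
    } else {
      # below the fine-stage threshold: the coarse-stage fit (and its
      # R^2 against the smoothed series) is carried forward unchanged
      fit$r2[v] <- coarse$r2[v]
    }
  }
  if (fwhm_params_mm > 0) {
    fitted_ok <- !is.na(fit$r2)
    pars <- as.matrix(fit[, c("x", "y", "sigma")])
    pars[!fitted_ok, ] <- NA
    sm <- surface_smooth(pars, graph, fwhm_params_mm)
    fit$x[fitted_ok] <- sm[fitted_ok, 1]
    fit$y[fitted_ok] <- sm[fitted_ok, 2]
    fit$sigma[fitted_ok] <- sm[fitted_ok, 3]
  }
  fit$ecc <- sqrt(fit$x^2 + fit$y^2)
  fit$polar <- wrap_angle_deg(atan2(fit$y, fit$x) * 180 / pi)
  fit
}

#' Write a fitted pRF map as CSV
#' @param map [fit_prf_map()] output.
#' @param path Output path.
#' @export
write_prf_map <- function(map, path) {
  utils::write.csv(map, path, row.names = FALSE)
  invisible(path)
}
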