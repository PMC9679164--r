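#' Paired polar-angle sample from two pRF maps
#'
#' Pairs per-vertex polar angle estimates from a rod-driven and a
#' cone-driven map, keeping only vertices whose fit exceeds the R-squared
#' threshold in *both* maps (the stricter pairing choice).
#'
#' @param rod_map,cone_map [fit_prf_map()] outputs (or any data frame with
#'   `vertex`, `polar`, `r2`).
#' @param r2_min Inclusion threshold applied to both maps.
#' @return Data frame with `vertex`, `theta` (rod angle, deg) and `phi`
#'   (cone angle, deg), both in (-180, 180].
#' @export
paired_angle_sample <- function(rod_map, cone_map, r2_min = 0.03) {
  rod <- threshold_by_r2(rod_map, r2_min)
  cone <- threshold_by_r2(cone_map, r2_min)
  shared <- intersect(rod$vertex, cone$vertex)
  data.frame(vertex = shared,
             theta = rod$polar[match(shared, rod$vertex)],
             phi = cone$polar[match(shared, cone$vertex)])
}

#' Orthogonal (total least squares) regression of paired angles
#'
#' Fits the line minimizing orthogonal distances: the first principal axis
#' of the centred (theta, phi) cloud, with the intercept through the
#' centroid. Unlike ordinary least squares, the slope is not attenuated by
#' noise in the x-variable, so identical maps with symmetric noise recover
#' slope 1.
#'
#' @param theta,phi Numeric vectors (deg), length >= 3.
#' @return A list with `slope` and `intercept`.
#' @export
orthogonal_regression <- function(theta, phi) {
  if (length(theta) != length(phi) || length(theta) < 3) {
    stop("need at least 3 paired observations")
  }
  m <- cbind(theta - mean(theta), phi - mean(phi))
  tv <- sum(m^2)
  if (tv < 1e-12) stop("zero total variance: regression undefined")
  e <- eigen(crossprod(m) / nrow(m), symmetric = TRUE)
  v <- e$vectors[, 1]
  if (abs(v[1]) < 1e-12) stop("vertical principal axis: slope undefined")
  slope <- v[2] / v[1]
  list(slope = slope, intercept = mean(phi) - slope * mean(theta))
}

circular_mean_deg <- function(a) {
  r <- a * pi / 180
  wrap_angle_deg(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

# level c minimizing sum(wrap(a - c)^2): the wrapped RSS is piecewise
# quadratic in c with breakpoints opposite each observation; scan every
# interval, taking the interior mean as its candidate minimizer
wrapped_rss_level <- function(a) {
  bp <- sort(unique(wrap_angle_deg(a + 180)))
  cand <- (bp + c(bp[-1], bp[1] + 360)) / 2
  cand <- wrap_angle_deg(c(cand, cand + vapply(cand, function(c0) {
    mean(wrap_angle_deg(a - c0))
  }, numeric(1)), circular_mean_deg(a)))
  rss <- vapply(cand, function(c0) sum(wrap_angle_deg(a - c0)^2),
                numeric(1))
  list(level = cand[which.min(rss)], rss = min(rss))
}

#' Akaike weight of the identity (correspondence) model
#'
#' Compares three accounts of the paired angles: the identity line
#' `phi = theta` (a structured cone map mirroring the rod map), a horizontal
#' line `phi = const` and a vertical line `theta = const` (unstructured data
#' in the cone or rod map respectively). By default angles are treated
#' linearly (unwrapped residuals, arithmetic-mean levels): an unstructured
#' cone map then costs the identity model the *sum* of both maps' angular
#' variances while the level models pay only one, which is what gives the
#' comparison its power to reject correspondence on noise-driven maps.
#' Wrapped residuals (`wrap = TRUE`, with levels fitted by minimizing the
#' wrapped RSS — AIC compares maximized likelihoods, so the level models
#' must be fitted, not centred at a summary statistic; or
#' `level = "circular_mean"`) respect the angular topology but cap the
#' identity residuals of independent maps at the same uniform plateau as
#' the level models, which weakens the test; they are provided as
#' documented options. With `AIC = n log(RSS/n) + 2k` (k = 1 for the
#' identity model, whose only parameter is the noise variance; k = 2 for
#' the level models), the returned weight is the identity model's relative
#' likelihood; values near 1 indicate strong evidence for rod-cone
#' correspondence.
#'
#' @param theta,phi Numeric angle vectors (deg), length >= 3.
#' @param wrap Wrap residuals to (-180, 180] (default `FALSE`: plain
#'   linear residuals and arithmetic-mean levels).
#' @param level For `wrap = TRUE`: `"fitted"` (wrapped-RSS-minimizing
#'   level) or `"circular_mean"`.
#' @return The identity-model Akaike weight in [0, 1], with attribute
#'   `weights` giving all three (identity, horizontal, vertical).
#' @export
aic_weight_identity <- function(theta, phi, wrap = FALSE,
                                level = c("fitted", "circular_mean")) {
  n <- length(theta)
  if (n != length(phi) || n < 3) stop("need at least 3 paired observations")
  level <- match.arg(level)
  if (!wrap) {
    rss <- c(identity = sum((phi - theta)^2),
             horizontal = sum((phi - mean(phi))^2),
             vertical = sum((theta - mean(theta))^2))
  } else if (level == "fitted") {
    rss <- c(identity = sum(wrap_angle_deg(phi - theta)^2),
             horizontal = wrapped_rss_level(phi)$rss,
             vertical = wrapped_rss_level(theta)$rss)
  } else {
    rss <- c(identity = sum(wrap_angle_deg(phi - theta)^2),
             horizontal = sum(wrap_angle_deg(phi -
                                               circular_mean_deg(phi))^2),
             vertical = sum(wrap_angle_deg(theta -
                                             circular_mean_deg(theta))^2))
  }
  rss <- pmax(rss, 1e-12)  # epsilon floor against perfect fits
  k <- c(identity = 1, horizontal = 2, vertical = 2)
  aic <- n * log(rss / n) + 2 * k
  w <- exp(-0.5 * (aic - min(aic)))
  w <- w / sum(w)
  structure(unname(w["identity"]), weights = w)
}

#' Fisher-Lee circular correlation coefficient
#'
#' Correlation for paired angular variables, invariant to adding a constant
#' rotation to either variable:
#' `T = sum_{i<j} sin(t_i - t_j) sin(p_i - p_j)` normalized by the square
#' root of the two within-variable sums of squared sines.
#'
#' @param theta,phi Numeric angle vectors (deg), length >= 3.
#' @return The coefficient in [-1, 1]; `NA` (with a warning) if either
#'   variable's angles are all equal.
#' @export
fisher_lee_correlation <- function(theta, phi) {
  n <- length(theta)
  if (n != length(phi) || n < 3) stop("need at least 3 paired observations")
  t_r <- theta * pi / 180; p_r <- phi * pi / 180
  a <- sin(t_r); b <- cos(t_r); c_ <- sin(p_r); d <- cos(p_r)
  # sum_{i<j} sin(ti-tj) sin(pi-pj) = (a.c)(b.d) - (a.d)(b.c)
  num <- sum(a * c_) * sum(b * d) - sum(a * d) * sum(b * c_)
  den_t <- sum(a^2) * sum(b^2) - sum(a * b)^2
  den_p <- sum(c_^2) * sum(d^2) - sum(c_ * d)^2
  eps <- 1e-12 * n^2
  if (den_t <= eps || den_p <= eps) {
    warning("degenerate angular spread: correlation undefined")
    return(NA_real_)
  }
  num / sqrt(den_t * den_p)
}

#' Permutation test for the Fisher-Lee correlation
#'
#' Two-sided permutation p-value obtained by shuffling `phi`:
#' `p = (1 + #(|CC_perm| >= |CC_obs|)) / (n_perm + 1)`.
#'
#' @param theta,phi Numeric angle vectors (deg).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed (reproducible).
#' @return A list with `cc`, `p` and `n_perm`.
#' @export
permutation_test_cc <- function(theta, phi, n_perm = 999, seed = 1) {
  if (n_perm < 100) stop("use at least 100 permutations")
  cc <- fisher_lee_correlation(theta, phi)
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    cc_p <- fisher_lee_correlation(theta, sample(phi))
    if (!is.na(cc_p) && abs(cc_p) >= abs(cc)) exceed <- exceed + 1L
  }
  list(cc = cc, p = (1 + exceed) / (n_perm + 1), n_perm = n_perm)
}

#' Full rod-cone correspondence summary for one paired-angle sample
#'
#' @param sample A [paired_angle_sample()] data frame (`theta`, `phi`).
#' @param n_perm Permutations for the correlation test (0 skips it).
#' @param seed Seed for the permutation test.
#' @return A one-row data frame: `slope`, `intercept`, `aic_w`, `cc_fl`,
#'   `cc_p`, `n_pairs`.
#' @export
correspondence_result <- function(sample, n_perm = 0, seed = 1) {
  n <- nrow(sample)
  if (n < 3) {
    return(data.frame(slope = NA_real_, intercept = NA_real_,
                      aic_w = NA_real_, cc_fl = NA_real_, cc_p = NA_real_,
                      n_pairs = n))
  }
  reg <- tryCatch(orthogonal_regression(sample$theta, sample$phi),
                  error = function(e) list(slope = NA_real_,
                                           intercept = NA_real_))
  cc <- suppressWarnings(fisher_lee_correlation(sample$theta, sample$phi))
  p <- NA_real_
  if (n_perm > 0 && !is.na(cc)) {
    p <- permutation_test_cc(sample$theta, sample$phi, n_perm, seed)$p
  }
  data.frame(slope = reg$slope, intercept = reg$intercept,
             aic_w = as.numeric(aic_weight_identity(sample$theta,
                                                    sample$phi)),
             cc_fl = cc, cc_p = p, n_pairs = n)
}

#' Linear correspondence for non-angular position estimates
#'
#' The same correspondence summary for x, y or eccentricity estimates,
#' which are not circular: unwrapped residuals and the Pearson correlation
#' in place of the Fisher-Lee coefficient.
#'
#' @param rod_values,cone_values Paired numeric vectors (length >= 3).
#' @return One-row data frame: `slope`, `intercept`, `aic_w`, `cor`, `n`.
#' @export
linear_correspondence <- function(rod_values, cone_values) {
  reg <- orthogonal_regression(rod_values, cone_values)
  data.frame(slope = reg$slope, intercept = reg$intercept,
             aic_w = as.numeric(aic_weight_identity(rod_values, cone_values,
                                                    wrap = FALSE)),
             cor = stats::cor(rod_values, cone_values),
             n = length(rod_values))
}

#' Normative envelope from control correspondence results
#'
#' Builds the normal-sighted benchmark: a 95% coverage ellipse for
#' (slope, intercept) from the controls' sample mean and covariance at the
#' chi-squared(2) radius, and the empirical 95% range of the Fisher-Lee
#' coefficients.
#'
#' @param control_results Data frame of [correspondence_result()] rows
#'   (>= 3 controls).
#' @param level Coverage level (default 0.95).
#' @return An object of class `normative_envelope` with `mean`, `cov`,
#'   `radius2`, `cc_range`, `level`.
#' @export
normative_range <- function(control_results, level = 0.95) {
  b <- cbind(control_results$slope, control_results$intercept)
  b <- b[stats::complete.cases(b), , drop = FALSE]
  if (nrow(b) < 3) stop("need at least 3 control results")
  s <- stats::cov(b)
  if (!is.finite(determinant(s)$modulus) || det(s) <= 0) {
    stop("singular control covariance: ellipse undefined")
  }
  cc <- control_results$cc_fl[!is.na(control_results$cc_fl)]
  structure(list(mean = colMeans(b), cov = s,
                 radius2 = stats::qchisq(level, df = 2),
                 cc_range = if (length(cc) >= 3) {
                   stats::quantile(cc, c((1 - level) / 2, (1 + level) / 2),
                                   names = FALSE)
                 } else c(NA_real_, NA_real_),
                 level = level),
            class = "normative_envelope")
}

#' Classify a correspondence result against the normative envelope
#'
#' @param envelope A [normative_range()] result.
#' @param result A one-row [correspondence_result()] data frame.
#' @return A list with `mahalanobis2`, `inside_ellipse`, `inside_cc_range`.
#' @export
classify_against_envelope <- function(envelope, result) {
  b <- c(result$slope, result$intercept)
  m2 <- if (any(is.na(b))) NA_real_ else
    drop(stats::mahalanobis(matrix(b, 1), envelope$mean, envelope$cov))
  in_cc <- if (is.na(result$cc_fl) || any(is.na(envelope$cc_range)))
    NA else
    result$cc_fl >= envelope$cc_range[1] & result$cc_fl <= envelope$cc_range[2]
  list(mahalanobis2 = m2,
       inside_ellipse = if (is.na(m2)) NA else m2 <= envelope$radius2,
       inside_cc_range = in_cc)
}
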