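#' Visual-field coverage map from a set of pRFs
#'
#' Renders every pRF as a peak-normalized Gaussian (value 1 at its centre)
#' in visual-field space and takes, at each grid point, the maximum density
#' across pRFs. Peak normalization (rather than unit volume) means one large
#' foveal pRF yields high coverage over a broad area, which is the intended
#' reading of this statistic. Coverage is monotone in the pRF set: adding a
#' pRF never decreases any value.
#'
#' @param prfs Data frame of (filtered) pRF parameters with `x`, `y`,
#'   `sigma`. An empty set gives an all-zero map.
#' @param max_eccentricity Half-width of the square grid (deg, default 8.6).
#' @param spacing Grid spacing (deg, default 0.1).
#' @return A list of class `coverage_map` with `x`, `y` (axes, deg) and
#'   `values` (length(x) x length(y) matrix in [0, 1]).
#' @export
coverage_map <- function(prfs, max_eccentricity = 8.6, spacing = 0.1) {
  ax <- seq(-max_eccentricity, max_eccentricity, by = spacing)
  vals <- matrix(0, length(ax), length(ax))
  if (nrow(prfs) > 0) {
    gx <- matrix(rep(ax, times = length(ax)), length(ax))
    gy <- matrix(rep(ax, each = length(ax)), length(ax))
    for (i in seq_len(nrow(prfs))) {
      g <- exp(-((gx - prfs$x[i])^2 + (gy - prfs$y[i])^2) /
                 (2 * prfs$sigma[i]^2))
      vals <- pmax(vals, g)
    }
  }
  structure(list(x = ax, y = ax, values = vals), class = "coverage_map")
}

#' Write a coverage map as a matrix CSV
#' @param map A [coverage_map()].
#' @param path Output path.
#' @export
write_coverage_map <- function(map, path) {
  m <- map$values
  dimnames(m) <- list(sprintf("%.3f", map$x), sprintf("%.3f", map$y))
  utils::write.csv(m, path)
  invisible(path)
}

#' Plot a coverage map as a heat map
#' @param x A [coverage_map()].
#' @param ... Passed to [graphics::image()].
#' @export
plot.coverage_map <- function(x, ...) {
  graphics::image(x$x, x$y, x$values, asp = 1, xlab = "x (deg)",
                  ylab = "y (deg)", ...)
  invisible(x)
}

#' pRF size-by-eccentricity profile
#'
#' Bins pRFs by eccentricity into half-open 1-degree bins over
#' `[0.5, 8.5)` and computes the median pRF size per bin. A bin is excluded
#' when its count falls below 10% of the count in the equivalent bin of the
#' reference (non-selective) condition; with no reference counts no bin is
#' excluded (with a warning).
#'
#' @param prfs Data frame with `ecc` and `sigma`.
#' @param reference_counts Optional per-bin counts from the non-selective
#'   condition of the same subject (length = number of bins).
#' @param bin_edges Bin edges (deg, default `seq(0.5, 8.5, by = 1)`).
#' @param exclusion_fraction Exclusion rule threshold (default 0.10).
#' @return Data frame of class `size_ecc_profile`: `bin_centre`,
#'   `median_sigma`, `n`, `excluded` (medians are `NA` for excluded bins).
#' @export
size_ecc_profile <- function(prfs, reference_counts = NULL,
                             bin_edges = seq(0.5, 8.5, by = 1),
                             exclusion_fraction = 0.10) {
  n_bins <- length(bin_edges) - 1L
  centres <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  idx <- findInterval(prfs$ecc, bin_edges, left.open = FALSE,
                      rightmost.closed = FALSE)
  idx[prfs$ecc >= bin_edges[length(bin_edges)]] <- NA
  idx[idx == 0] <- NA
  n <- tabulate(idx, nbins = n_bins)
  med <- vapply(seq_len(n_bins), function(b) {
    s <- prfs$sigma[!is.na(idx) & idx == b]
    if (length(s) == 0) NA_real_ else stats::median(s)
  }, numeric(1))
  if (is.null(reference_counts)) {
    warning("no reference counts supplied: no bin exclusion applied")
    excluded <- n == 0
  } else {
    if (length(reference_counts) != n_bins) {
      stop("reference_counts length must match the number of bins")
    }
    excluded <- n < exclusion_fraction * reference_counts | n == 0
  }
  med[excluded] <- NA_real_
  out <- data.frame(bin_centre = centres, median_sigma = med, n = n,
                    excluded = excluded)
  class(out) <- c("size_ecc_profile", class(out))
  out
}

#' Group envelope of size-eccentricity profiles
#'
#' Per-bin mean with a t-based confidence interval and the empirical
#' percentile range across profiles. A profile missing (excluded) in a bin
#' is omitted from that bin only.
#'
#' @param profiles List of [size_ecc_profile()] data frames on identical
#'   bins (>= 3 profiles).
#' @param level Coverage level (default 0.95).
#' @return Data frame: `bin_centre`, `n_profiles`, `mean`, `ci_lo`, `ci_hi`,
#'   `range_lo`, `range_hi`.
#' @export
group_envelope <- function(profiles, level = 0.95) {
  if (length(profiles) < 3) stop("need at least 3 profiles")
  centres <- profiles[[1]]$bin_centre
  vals <- vapply(profiles, function(p) {
    stopifnot(isTRUE(all.equal(p$bin_centre, centres)))
    p$median_sigma
  }, numeric(length(centres)))
  per_bin <- function(b) {
    v <- vals[b, ]
    v <- v[!is.na(v)]
    k <- length(v)
    if (k == 0) return(c(0, rep(NA_real_, 5)))
    m <- mean(v)
    if (k == 1) return(c(1, m, NA, NA, m, m))
    half <- stats::qt((1 + level) / 2, df = k - 1) * stats::sd(v) / sqrt(k)
    rng <- stats::quantile(v, c((1 - level) / 2, (1 + level) / 2),
                           names = FALSE)
    c(k, m, m - half, m + half, rng[1], rng[2])
  }
  stats_m <- t(vapply(seq_along(centres), per_bin, numeric(6)))
  data.frame(bin_centre = centres, n_profiles = stats_m[, 1],
             mean = stats_m[, 2], ci_lo = stats_m[, 3], ci_hi = stats_m[, 4],
             range_lo = stats_m[, 5], range_hi = stats_m[, 6])
}
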