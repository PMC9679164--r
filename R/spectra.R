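#' Spectral curves
#'
#' A spectral curve is a tabulated function of wavelength: a display
#' primary's spectral power distribution (SPD) or a photoreceptor spectral
#' sensitivity. Wavelengths must form a strictly increasing, uniformly
#' spaced grid in nanometres and values must be non-negative.
#'
#' @param wavelength_nm Numeric vector of wavelengths (nm), strictly
#'   increasing with constant step.
#' @param value Numeric vector of the same length, non-negative.
#' @return An object of class `spectral_curve` (a list with elements
#'   `wavelength_nm` and `value`).
#' @export
spectral_curve <- function(wavelength_nm, value) {
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  if (length(wavelength_nm) != length(value)) {
    stop("wavelength and value must have equal length")
  }
  if (length(wavelength_nm) < 2L) stop("need at least two samples")
  d <- diff(wavelength_nm)
  if (any(d <= 0)) stop("wavelength grid must be strictly increasing")
  if (max(d) - min(d) > 1e-6 * mean(d)) {
    stop("wavelength grid must be uniformly spaced")
  }
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("spectral values must be finite and non-negative")
  }
  structure(list(wavelength_nm = wavelength_nm, value = value),
            class = "spectral_curve")
}

#' @method print spectral_curve
#' @export
print.spectral_curve <- function(x, ...) {
  cat(sprintf("<spectral_curve: %d samples, %.0f-%.0f nm, peak %.4g>\n",
              length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), max(x$value)))
  invisible(x)
}

#' Resample a spectral curve onto a new wavelength grid
#'
#' Linear interpolation; wavelengths outside the tabulated range get zero.
#'
#' @param curve A [spectral_curve()].
#' @param grid_nm Target wavelength grid (uniform, increasing).
#' @return A `spectral_curve` on `grid_nm`.
#' @export
resample_spectrum <- function(curve, grid_nm) {
  v <- stats::approx(curve$wavelength_nm, curve$value, xout = grid_nm,
                     method = "linear", rule = 1)$y
  v[is.na(v)] <- 0
  spectral_curve(grid_nm, v)
}

#' Default colorimetric wavelength grid (390-780 nm at 1 nm)
#' @return Numeric vector of wavelengths in nm.
#' @export
default_wavelength_grid <- function() seq(390, 780, by = 1)

#' Parametric photopigment template
#'
#' Generates a smooth, peak-normalized spectral sensitivity as a Gaussian in
#' log wavelength, a standard low-parameter stand-in for photopigment
#' absorbance templates. Adequate for fully synthetic calibration work; not
#' a measured observer.
#'
#' @param peak_nm Wavelength of maximum sensitivity (nm).
#' @param bandwidth Gaussian SD in log10-wavelength units (default 0.035,
#'   giving realistic ~100 nm half-height widths in the visible range).
#' @param grid_nm Wavelength grid (default [default_wavelength_grid()]).
#' @return A peak-normalized `spectral_curve`.
#' @export
photopigment_template <- function(peak_nm, bandwidth = 0.035,
                                  grid_nm = default_wavelength_grid()) {
  z <- (log10(grid_nm) - log10(peak_nm)) / bandwidth
  spectral_curve(grid_nm, exp(-0.5 * z^2))
}

#' Synthetic standard-observer receptor set
#'
#' Builds the four photoreceptor sensitivity curves (L, M, S cones and rod)
#' from the photopigment template at canonical peak wavelengths
#' (L 566 nm, M 541 nm, S 441 nm, rod 507 nm). These are synthetic template
#' curves, not tabulated psychophysical fundamentals; they reproduce the
#' qualitative spectral overlap structure that silent substitution relies on.
#'
#' @param grid_nm Wavelength grid.
#' @return A [receptor_set()].
#' @export
synthetic_receptor_set <- function(grid_nm = default_wavelength_grid()) {
  receptor_set(
    L   = photopigment_template(566, grid_nm = grid_nm),
    M   = photopigment_template(541, grid_nm = grid_nm),
    S   = photopigment_template(441, grid_nm = grid_nm),
    rod = photopigment_template(507, grid_nm = grid_nm)
  )
}

#' Photoreceptor sensitivity set
#'
#' @param L,M,S,rod Peak-normalized [spectral_curve()] objects. Curves not
#'   peaking at 1 are renormalized.
#' @return An object of class `receptor_set`.
#' @export
receptor_set <- function(L, M, S, rod) {
  curves <- list(L = L, M = M, S = S, rod = rod)
  curves <- lapply(curves, function(cv) {
    stopifnot(inherits(cv, "spectral_curve"))
    pk <- max(cv$value)
    if (pk <= 0) stop("receptor sensitivity is identically zero")
    spectral_curve(cv$wavelength_nm, cv$value / pk)
  })
  structure(curves, class = "receptor_set")
}

#' Display model
#'
#' A three-primary display: the spectral power distribution of each channel
#' at maximum drive, a per-channel gamma exponent mapping drive in [0,1] to
#' relative radiance (1 = linear), and a per-channel scalar attenuation for
#' mirror / neutral-density transmission.
#'
#' @param red,green,blue [spectral_curve()] SPDs at full drive.
#' @param gamma Numeric length-3 positive exponents (drive^gamma = radiance),
#'   recycled from length 1. Maps 0 to 0 and 1 to 1 monotonically.
#' @param attenuation Numeric length-3 in (0, 1], recycled from length 1.
#' @return An object of class `display_model`.
#' @export
display_model <- function(red, green, blue, gamma = 1, attenuation = 1) {
  gamma <- rep_len(as.numeric(gamma), 3L)
  attenuation <- rep_len(as.numeric(attenuation), 3L)
  if (any(gamma <= 0)) stop("gamma exponents must be positive")
  if (any(attenuation <= 0 | attenuation > 1)) {
    stop("attenuation must lie in (0, 1]")
  }
  prim <- list(R = red, G = green, B = blue)
  for (p in prim) stopifnot(inherits(p, "spectral_curve"))
  structure(list(primary_spds = prim, gamma = gamma,
                 attenuation = attenuation),
            class = "display_model")
}

#' Synthetic LCD display model
#'
#' Three Gaussian primaries (R 611 nm, G 549 nm, B 465 nm) with realistic
#' bandwidths, a mildly non-canonical gamma, and unit attenuation. A
#' synthetic stand-in for a measured LCD used throughout tests and examples.
#'
#' @param gamma Per-channel gamma exponent(s) (default 2.2).
#' @param attenuation Per-channel transmission (default 1).
#' @param peak_nm Numeric length-3 primary peak wavelengths.
#' @param sd_nm Numeric length-3 spectral widths (SD, nm).
#' @param grid_nm Wavelength grid.
#' @return A [display_model()].
#' @export
synthetic_display_model <- function(gamma = 2.2, attenuation = 1,
                                    peak_nm = c(611, 549, 465),
                                    sd_nm = c(18, 25, 16),
                                    grid_nm = default_wavelength_grid()) {
  g <- function(pk, sd) {
    spectral_curve(grid_nm, exp(-0.5 * ((grid_nm - pk) / sd)^2))
  }
  display_model(red = g(peak_nm[1], sd_nm[1]), green = g(peak_nm[2], sd_nm[2]),
                blue = g(peak_nm[3], sd_nm[3]), gamma = gamma,
                attenuation = attenuation)
}

#' Read a spectral curve from two-column delimited text
#'
#' Expected format: two numeric columns (wavelength_nm, value), whitespace,
#' comma or tab separated; lines starting with `#` are comments.
#'
#' @param path File path.
#' @return A [spectral_curve()].
#' @export
read_spectral_curve <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           sep = "", col.names = c("wavelength_nm", "value"))
  if (ncol(tab) < 2L) stop("expected two columns: wavelength_nm, value")
  spectral_curve(tab$wavelength_nm, tab$value)
}

#' Write a spectral curve as two-column text
#' @param curve A [spectral_curve()].
#' @param path Output path.
#' @export
write_spectral_curve <- function(curve, path) {
  utils::write.table(
    data.frame(wavelength_nm = curve$wavelength_nm, value = curve$value),
    path, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load the shipped synthetic receptor fundamentals
#'
#' Reads the synthetic template fundamentals stored as plain-text fixtures
#' under `inst/extdata` (generated by [photopigment_template()]).
#'
#' @return A [receptor_set()].
#' @export
load_synthetic_fundamentals <- function() {
  f <- function(name) {
    read_spectral_curve(system.file("extdata",
      sprintf("fundamental_%s_synthetic.txt", name), package = "retinomap",
      mustWork = TRUE))
  }
  receptor_set(L = f("l"), M = f("m"), S = f("s"), rod = f("rod"))
}
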