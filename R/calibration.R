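#' Build the receptor excitation matrix of a display
#'
#' Computes the 4x3 matrix giving the excitation of each photoreceptor
#' (rows L, M, S, rod) per unit linear drive of each display channel
#' (columns R, G, B). Entry (r, c) is the Riemann sum of the channel SPD
#' times the receptor sensitivity over the common wavelength grid, scaled
#' by the channel attenuation. All spectra are resampled onto `grid_nm` by
#' linear interpolation.
#'
#' @param display A [display_model()].
#' @param receptors A [receptor_set()].
#' @param grid_nm Common wavelength grid (default 390-780 nm at 1 nm).
#' @return A 4x3 numeric matrix with dimnames
#'   `list(c("L","M","S","rod"), c("R","G","B"))`.
#' @export
build_excitation_matrix <- function(display, receptors,
                                    grid_nm = default_wavelength_grid()) {
  stopifnot(inherits(display, "display_model"),
            inherits(receptors, "receptor_set"))
  rng_overlap <- function(cv) {
    max(cv$wavelength_nm) >= min(grid_nm) &&
      min(cv$wavelength_nm) <= max(grid_nm)
  }
  all_curves <- c(display$primary_spds, unclass(receptors))
  if (!all(vapply(all_curves, rng_overlap, logical(1)))) {
    stop("spectra do not overlap the integration wavelength grid")
  }
  dl <- grid_nm[2] - grid_nm[1]
  spd <- vapply(display$primary_spds,
                function(cv) resample_spectrum(cv, grid_nm)$value,
                numeric(length(grid_nm)))
  sens <- vapply(unclass(receptors),
                 function(cv) resample_spectrum(cv, grid_nm)$value,
                 numeric(length(grid_nm)))
  m <- t(sens) %*% spd * dl
  m <- sweep(m, 2, display$attenuation, `*`)
  dimnames(m) <- list(c("L", "M", "S", "rod"), c("R", "G", "B"))
  m
}

#' Linearize display drive through the gamma model
#' @param display A [display_model()].
#' @param drive Numeric length-3 drive in [0,1] (R, G, B).
#' @return Linear radiance fractions in [0,1].
#' @export
linearize_drive <- function(display, drive) {
  drive <- as.numeric(drive)
  if (length(drive) != 3L) stop("drive must have length 3")
  if (any(drive < 0 | drive > 1)) stop("drive must lie in [0, 1]")
  drive^display$gamma
}

delinearize_drive <- function(display, linear) {
  linear <- pmin(pmax(linear, 0), 1)
  linear^(1 / display$gamma)
}

#' Receptor excitations produced by a drive setting
#'
#' Linearizes the drive through the per-channel gamma and applies the
#' excitation matrix.
#'
#' @inheritParams build_excitation_matrix
#' @param drive Numeric length-3 RGB drive in [0,1].
#' @param matrix Optional precomputed excitation matrix.
#' @return Named numeric length-4 vector (L, M, S, rod).
#' @export
receptor_excitation <- function(display, receptors, drive, matrix = NULL) {
  if (is.null(matrix)) matrix <- build_excitation_matrix(display, receptors)
  drop(matrix %*% linearize_drive(display, drive))
}

#' Michelson contrast between two excitation levels
#'
#' @param e_target,e_background Non-negative excitation values (vectors are
#'   handled elementwise).
#' @return `|e_t - e_b| / (e_t + e_b)`, in [0, 1].
#' @export
michelson_contrast <- function(e_target, e_background) {
  if (any(e_target < 0) || any(e_background < 0)) {
    stop("excitations must be non-negative")
  }
  s <- e_target + e_background
  if (any(s == 0)) stop("both excitations are zero: contrast undefined")
  abs(e_target - e_background) / s
}

signed_contrast <- function(e_target, e_background) {
  (e_target - e_background) / (e_target + e_background)
}

#' Chromatic pair constructor
#'
#' A background and target drive plus the per-receptor signed Michelson
#' contrasts they induce (positive = target excitation above background).
#'
#' @param background_drive,target_drive Length-3 RGB drives in [0,1].
#' @param receptor_contrasts Named length-4 numeric (L, M, S, rod), signed.
#' @return An object of class `chromatic_pair`.
#' @export
chromatic_pair <- function(background_drive, target_drive, receptor_contrasts) {
  stopifnot(length(background_drive) == 3L, length(target_drive) == 3L,
            all(background_drive >= 0 & background_drive <= 1),
            all(target_drive >= 0 & target_drive <= 1))
  structure(list(background_drive = as.numeric(background_drive),
                 target_drive = as.numeric(target_drive),
                 receptor_contrasts = receptor_contrasts),
            class = "chromatic_pair")
}

#' @method print chromatic_pair
#' @export
print.chromatic_pair <- function(x, ...) {
  cat("<chromatic_pair>\n  background:", sprintf("%.4f", x$background_drive),
      "\n  target:    ", sprintf("%.4f", x$target_drive), "\n  contrasts: ",
      paste(names(x$receptor_contrasts),
            sprintf("%.6f", x$receptor_contrasts), collapse = "  "), "\n")
  invisible(x)
}

#' Recompute the receptor contrasts of a chromatic pair
#' @param pair A [chromatic_pair()].
#' @inheritParams build_excitation_matrix
#' @param matrix Optional precomputed excitation matrix.
#' @return Named length-4 signed contrast vector.
#' @export
pair_contrasts <- function(pair, display, receptors, matrix = NULL) {
  if (is.null(matrix)) matrix <- build_excitation_matrix(display, receptors)
  e_b <- receptor_excitation(display, receptors, pair$background_drive, matrix)
  e_t <- receptor_excitation(display, receptors, pair$target_drive, matrix)
  signed_contrast(e_t, e_b)
}

# Gamut scaling: largest s >= 0 with lin + s*delta in [0,1] per channel.
# Returns the bound and the first channel that clips.
gamut_limit <- function(lin, delta, channels = c("R", "G", "B")) {
  s_max <- rep(Inf, length(lin))
  pos <- delta > 0
  neg <- delta < 0
  s_max[pos] <- (1 - lin[pos]) / delta[pos]
  s_max[neg] <- (0 - lin[neg]) / delta[neg]
  list(s = min(s_max), channel = channels[which.min(s_max)])
}

solve_pair_along <- function(display, receptors, matrix, background_drive,
                             delta_lin, target_fn, target_value, what) {
  lin_b <- linearize_drive(display, background_drive)
  e_b <- drop(matrix %*% lin_b)
  contrast_at <- function(s) {
    e_t <- drop(matrix %*% (lin_b + s * delta_lin))
    signed_contrast(e_t, e_b)
  }
  if (target_value == 0) {
    return(chromatic_pair(background_drive, background_drive,
                          stats::setNames(rep(0, 4), rownames(matrix))))
  }
  lim <- gamut_limit(lin_b, delta_lin)
  if (!is.finite(lim$s) || lim$s <= 0) {
    stop(sprintf("background is at the gamut edge of channel %s", lim$channel))
  }
  f <- function(s) target_fn(contrast_at(s)) - target_value
  if (f(lim$s) < 0) {
    stop(sprintf(
      "requested %s contrast %.4g exceeds the display gamut (limited by channel %s; maximum attainable %.4g)",
      what, target_value, lim$channel, target_fn(contrast_at(lim$s))))
  }
  s <- stats::uniroot(f, c(0, lim$s), tol = 1e-14)$root
  lin_t <- lin_b + s * delta_lin
  target_drive <- delinearize_drive(display, lin_t)
  # unmodulated channels keep the background drive exactly (no gamma
  # round-trip error)
  target_drive[delta_lin == 0] <- background_drive[delta_lin == 0]
  chromatic_pair(background_drive, target_drive, contrast_at(s))
}

#' Solve a cone-isolating (rod-silent) chromatic pair
#'
#' Finds a target drive that leaves rod excitation identical to the
#' background while inducing the requested mean L/M-cone Michelson contrast.
#' Only the red and green channels are varied: the modulation direction is
#' the one-dimensional rod-null direction in the linearized red-green plane,
#' so the blue drive is unchanged, and the step along it is solved so that
#' the mean of the L- and M-cone Michelson contrasts equals
#' `target_lm_contrast`. The pair is not (and cannot be) S-cone silent.
#'
#' @inheritParams build_excitation_matrix
#' @param background_drive Length-3 RGB background drive in [0,1]
#'   (default mid-grey 0.5).
#' @param target_lm_contrast Requested mean of the L- and M-cone Michelson
#'   contrasts (>= 0).
#' @param matrix Optional precomputed excitation matrix.
#' @param bidirectional If `TRUE`, return a symmetric increment/decrement
#'   pair around the background (background replaced by the decrement side);
#'   default `FALSE` (one-sided modulation from the background).
#' @return A [chromatic_pair()] with signed per-receptor contrasts.
#' @export
solve_cone_isolating_pair <- function(display, receptors,
                                      background_drive = rep(0.5, 3),
                                      target_lm_contrast,
                                      matrix = NULL, bidirectional = FALSE) {
  if (target_lm_contrast < 0) stop("target contrast must be non-negative")
  if (is.null(matrix)) matrix <- build_excitation_matrix(display, receptors)
  # rod-null direction in the (R, G) linear plane
  rodR <- matrix["rod", "R"]; rodG <- matrix["rod", "G"]
  if (rodR == 0 && rodG == 0) {
    stop("degenerate rod-null direction: rods are insensitive to R and G")
  }
  d <- c(rodG, -rodR, 0)
  d <- d / sqrt(sum(d^2))
  # if R and G columns are proportional, the rod-null direction moves no cone
  if (max(abs(matrix[c("L", "M"), ] %*% d)) <
      1e-12 * max(abs(matrix))) {
    stop("degenerate rod-null direction: R and G columns are proportional")
  }
  # orient toward increasing summed L+M excitation
  if (sum(matrix[c("L", "M"), ] %*% d) < 0) d <- -d
  mean_lm <- function(contrasts) mean(abs(contrasts[c("L", "M")]))
  if (bidirectional) {
    half <- solve_pair_along(display, receptors, matrix, background_drive,
                             d, mean_lm, target_lm_contrast / 2, "mean L/M")
    lin_b <- linearize_drive(display, background_drive)
    lin_t <- linearize_drive(display, half$target_drive)
    lin_lo <- lin_b - (lin_t - lin_b)
    if (any(lin_lo < -1e-12) || any(lin_lo > 1 + 1e-12)) {
      stop("decrement side of the bidirectional pair leaves the gamut")
    }
    lo_drive <- delinearize_drive(display, lin_lo)
    e_lo <- receptor_excitation(display, receptors, lo_drive, matrix)
    e_hi <- receptor_excitation(display, receptors, half$target_drive, matrix)
    return(chromatic_pair(lo_drive, half$target_drive,
                          signed_contrast(e_hi, e_lo)))
  }
  solve_pair_along(display, receptors, matrix, background_drive, d,
                   mean_lm, target_lm_contrast, "mean L/M")
}

#' Solve a rod-isolating (L/M-cone-silent) chromatic pair
#'
#' Modulates along the null space of the L and M rows of the excitation
#' matrix (the cross product of the two rows), so L- and M-cone excitations
#' stay fixed while rods see the requested Michelson contrast. The S-cone
#' contrast is reported but unconstrained: with three primaries only two
#' receptor classes can be silenced.
#'
#' @inheritParams solve_cone_isolating_pair
#' @param target_rod_contrast Requested rod Michelson contrast (>= 0).
#' @return A [chromatic_pair()].
#' @export
solve_rod_isolating_pair <- function(display, receptors,
                                     background_drive = rep(0.5, 3),
                                     target_rod_contrast,
                                     matrix = NULL) {
  if (target_rod_contrast < 0) stop("target contrast must be non-negative")
  if (is.null(matrix)) matrix <- build_excitation_matrix(display, receptors)
  a <- matrix["L", ]; b <- matrix["M", ]
  d <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12 * max(abs(matrix))^2) {
    stop("L and M rows are proportional: the silencing null space is degenerate")
  }
  d <- d / nd
  if (sum(matrix["rod", ] * d) < 0) d <- -d
  solve_pair_along(display, receptors, matrix, background_drive, d,
                   function(ct) abs(ct[["rod"]]), target_rod_contrast, "rod")
}

#' Validate the residual contrasts of a chromatic pair
#'
#' Recomputes per-receptor contrasts from the stored drives under a given
#' display/receptor model (possibly different from the one used to solve,
#' e.g. with perturbed spectra to emulate measurement error) and checks the
#' residual Michelson contrast of each nominally silenced receptor against
#' a tolerance.
#'
#' @param pair A [chromatic_pair()].
#' @inheritParams build_excitation_matrix
#' @param silenced Character vector of receptor names meant to be silent
#'   (subset of L, M, S, rod); may be empty.
#' @param tol Pass tolerance on the absolute residual contrast.
#' @return A list with `contrasts` (signed, all receptors), `residuals`
#'   (named absolute contrasts of the silenced receptors), `tol`, and `pass`.
#' @export
validate_pair <- function(pair, display, receptors, silenced,
                          tol = 1e-6) {
  stopifnot(all(silenced %in% c("L", "M", "S", "rod")))
  ct <- pair_contrasts(pair, display, receptors)
  res <- abs(ct[silenced])
  list(contrasts = ct, residuals = res, tol = tol,
       pass = length(res) == 0L || all(res < tol))
}

#' Write a chromatic pair as a delimited table
#' @param pair A [chromatic_pair()].
#' @param path Output CSV path.
#' @export
write_chromatic_pair <- function(pair, path) {
  df <- data.frame(
    quantity = c("background_R", "background_G", "background_B",
                 "target_R", "target_G", "target_B",
                 paste0("contrast_", names(pair$receptor_contrasts))),
    value = c(pair$background_drive, pair$target_drive,
              unname(pair$receptor_contrasts)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
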