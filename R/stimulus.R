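#' Ring-and-wedge protocol configuration
#'
#' Geometry and timing of the combined ring + wedge retinotopic mapping run:
#' an expanding/contracting ring (6 cycles of 48 s, logarithmic eccentricity
#' scaling) and a rotating 20-degree wedge (8 cycles of 36 s), with 20-s
#' fixation baselines at the start, mid-point and end, at TR = 1 s, for a
#' total of 348 frames. The ring and wedge stimulation totals must agree
#' (6 x 48 = 8 x 36 = 288 s).
#'
#' @param max_eccentricity Maximum stimulated eccentricity (deg, default 8.6).
#' @param min_eccentricity Smallest ring centre eccentricity (deg, default 0.5).
#' @param tr_s Repetition time / frame duration (s).
#' @param ring_cycles,ring_period_s Ring cycles per run and cycle period (s).
#' @param wedge_cycles,wedge_period_s Wedge cycles per run and period (s).
#' @param wedge_width_deg Angular width of the wedge (deg).
#' @param baseline_s Duration of each fixation baseline (s).
#' @param grid_resolution Pixels per degree of the visual-field grid.
#' @param ring_width_scale Ring width as a fraction of its centre
#'   eccentricity (log-scaled annulus).
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(max_eccentricity = 8.6, min_eccentricity = 0.5,
                            tr_s = 1, ring_cycles = 6, ring_period_s = 48,
                            wedge_cycles = 8, wedge_period_s = 36,
                            wedge_width_deg = 20, baseline_s = 20,
                            grid_resolution = 4, ring_width_scale = 0.5) {
  cfg <- list(max_eccentricity = max_eccentricity,
              min_eccentricity = min_eccentricity, tr_s = tr_s,
              ring_cycles = ring_cycles, ring_period_s = ring_period_s,
              wedge_cycles = wedge_cycles, wedge_period_s = wedge_period_s,
              wedge_width_deg = wedge_width_deg, baseline_s = baseline_s,
              grid_resolution = grid_resolution,
              ring_width_scale = ring_width_scale)
  if (any(unlist(cfg) <= 0)) stop("all protocol parameters must be positive")
  if (cfg$min_eccentricity >= cfg$max_eccentricity) {
    stop("min_eccentricity must be below max_eccentricity")
  }
  ring_total <- ring_cycles * ring_period_s
  wedge_total <- wedge_cycles * wedge_period_s
  if (ring_total != wedge_total) {
    stop(sprintf("ring (%g s) and wedge (%g s) stimulation totals differ",
                 ring_total, wedge_total))
  }
  cfg$stim_s <- ring_total
  cfg$total_s <- ring_total + 3 * baseline_s
  cfg$n_frames <- as.integer(round(cfg$total_s / tr_s))
  structure(cfg, class = "protocol_config")
}

#' Ring eccentricity schedule
#'
#' Per-stimulation-frame (inner, outer) annulus radii. The ring centre
#' follows a logarithmic progression from `min_eccentricity` up to the
#' eccentricity whose outer edge touches `max_eccentricity` over each cycle;
#' ring width scales proportionally with centre eccentricity
#' (`ring_width_scale`), and the direction flag reverses the progression.
#'
#' @param config A [protocol_config()].
#' @param direction `"expanding"` or `"contracting"`.
#' @return Data frame with one row per stimulation frame: `frame`, `centre`,
#'   `inner`, `outer` (deg).
#' @export
ring_eccentricity_schedule <- function(config, direction = "expanding") {
  direction <- match.arg(direction, c("expanding", "contracting"))
  n_cycle <- as.integer(round(config$ring_period_s / config$tr_s))
  # centre whose outer edge (centre * (1 + scale/2)) reaches max ecc
  c_max <- config$max_eccentricity / (1 + config$ring_width_scale / 2)
  centre <- exp(seq(log(config$min_eccentricity), log(c_max),
                    length.out = n_cycle))
  if (direction == "contracting") centre <- rev(centre)
  centre <- rep(centre, config$ring_cycles)
  half_w <- config$ring_width_scale * centre / 2
  data.frame(frame = seq_along(centre), centre = centre,
             inner = pmax(0, centre - half_w), outer = centre + half_w)
}

#' Wedge angle schedule
#'
#' Per-stimulation-frame wedge centre angle. The wedge advances
#' `360 / (wedge_period_s / tr_s)` degrees per frame (10 deg at the default
#' 36-s period and 1-s TR), anticlockwise for positive rotation, wrapping
#' modulo 360. Angles use the package convention: 0 = right horizontal
#' meridian, anticlockwise positive, reported in (-180, 180].
#'
#' @param config A [protocol_config()].
#' @param direction `"anticlockwise"` or `"clockwise"`.
#' @param start_angle Wedge centre at the first stimulation frame (deg).
#' @return Data frame with `frame` and `angle` (deg, (-180, 180]).
#' @export
wedge_angle_schedule <- function(config, direction = "anticlockwise",
                                 start_angle = 90) {
  direction <- match.arg(direction, c("anticlockwise", "clockwise"))
  n_cycle <- as.integer(round(config$wedge_period_s / config$tr_s))
  step <- 360 / n_cycle
  if (direction == "clockwise") step <- -step
  n <- n_cycle * config$wedge_cycles
  angle <- wrap_angle_deg(start_angle + (seq_len(n) - 1L) * step)
  data.frame(frame = seq_len(n), angle = angle)
}

#' Wrap angles in degrees to (-180, 180]
#' @param a Numeric angles (deg).
#' @return Wrapped angles in (-180, 180].
#' @export
wrap_angle_deg <- function(a) {
  w <- a - 360 * floor((a + 180) / 360)
  w[w == -180] <- 180
  w
}

# pixel-centre coordinates of the square visual-field grid
aperture_grid <- function(config) {
  n <- as.integer(round(2 * config$max_eccentricity * config$grid_resolution))
  step <- 2 * config$max_eccentricity / n
  ax <- seq(-config$max_eccentricity + step / 2,
            config$max_eccentricity - step / 2, length.out = n)
  list(x = rep(ax, times = n), y = rep(ax, each = n), n = n, step = step)
}

#' Compose a full ring-and-wedge run
#'
#' Builds the per-TR binary aperture masks of one run: the union of the ring
#' annulus and the rotating wedge on a square visual-field grid spanning
#' +/- `max_eccentricity`, with 20-s all-off fixation baselines at the
#' start, mid-point and end. Wedge masks are half-open in angle
#' (`[angle - w/2, angle + w/2)`) so opposite frames never double-count the
#' wrap; no pixel beyond `max_eccentricity` is ever on.
#'
#' @param config A [protocol_config()].
#' @param ring_direction,wedge_direction Direction flags passed to the
#'   schedules.
#' @param wedge_start_angle Wedge centre angle at the first stimulation frame.
#' @return An object of class `aperture_sequence`: a list with `masks`
#'   (T x P 0/1 matrix, pixels in column-major grid order), `x`, `y` (pixel
#'   centre coordinates, deg), `frame_table` (frame, time_s, ring_inner,
#'   ring_outer, wedge_angle, baseline), and `config`.
#' @export
compose_run <- function(config = protocol_config(),
                        ring_direction = "expanding",
                        wedge_direction = "anticlockwise",
                        wedge_start_angle = 90) {
  ring <- ring_eccentricity_schedule(config, ring_direction)
  wedge <- wedge_angle_schedule(config, wedge_direction, wedge_start_angle)
  if (nrow(ring) != nrow(wedge)) {
    stop("ring and wedge schedules have different lengths")
  }
  n_stim <- nrow(ring)
  n_base <- as.integer(round(config$baseline_s / config$tr_s))
  half <- n_stim %/% 2L
  # frame layout: baseline | first half | baseline | second half | baseline
  stim_idx <- c(rep(NA_integer_, n_base), seq_len(half),
                rep(NA_integer_, n_base), seq(half + 1L, n_stim),
                rep(NA_integer_, n_base))
  n_frames <- length(stim_idx)
  if (n_frames != config$n_frames) {
    stop("composed frame count does not match the protocol configuration")
  }
  grid <- aperture_grid(config)
  r <- sqrt(grid$x^2 + grid$y^2)
  theta <- atan2(grid$y, grid$x) * 180 / pi
  in_field <- r <= config$max_eccentricity
  masks <- matrix(0, nrow = n_frames, ncol = length(r))
  half_w <- config$wedge_width_deg / 2
  for (f in seq_len(n_frames)) {
    s <- stim_idx[f]
    if (is.na(s)) next
    ring_on <- r >= ring$inner[s] & r <= ring$outer[s]
    d <- wrap_angle_deg(theta - wedge$angle[s])
    wedge_on <- d >= -half_w & d < half_w
    masks[f, ] <- as.numeric((ring_on | wedge_on) & in_field)
  }
  frame_table <- data.frame(
    frame = seq_len(n_frames),
    time_s = (seq_len(n_frames) - 1L) * config$tr_s,
    ring_inner = ifelse(is.na(stim_idx), NA, ring$inner[stim_idx]),
    ring_outer = ifelse(is.na(stim_idx), NA, ring$outer[stim_idx]),
    wedge_angle = ifelse(is.na(stim_idx), NA, wedge$angle[stim_idx]),
    baseline = is.na(stim_idx))
  structure(list(masks = masks,
                 masks_sparse = methods::as(Matrix::Matrix(masks,
                                                           sparse = TRUE),
                                            "CsparseMatrix"),
                 x = grid$x, y = grid$y,
                 frame_table = frame_table, config = config),
            class = "aperture_sequence")
}

#' @method print aperture_sequence
#' @export
print.aperture_sequence <- function(x, ...) {
  cat(sprintf(
    "<aperture_sequence: %d frames, %d px (%.1f px/deg, +/-%.1f deg), %d baseline frames>\n",
    nrow(x$masks), ncol(x$masks), x$config$grid_resolution,
    x$config$max_eccentricity, sum(x$frame_table$baseline)))
  invisible(x)
}

#' Write the frame table of an aperture sequence as CSV
#' @param apertures An [compose_run()] result.
#' @param path Output path.
#' @export
write_frame_table <- function(apertures, path) {
  utils::write.csv(apertures$frame_table, path, row.names = FALSE)
  invisible(path)
}
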