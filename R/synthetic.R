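#' Cortical sheet graph
#'
#' A synthetic stand-in for a reconstructed cortical surface: vertices on a
#' 2-D lattice (positions in mm) with symmetric adjacency, a hemisphere and
#' a region label per vertex. Geodesic distances are precomputed at
#' construction for surface smoothing.
#'
#' @param vertices Data frame with columns `vertex`, `hemi`, `region`,
#'   `x_mm`, `y_mm`.
#' @param edges Two-column integer matrix of undirected edges (vertex ids).
#' @return An object of class `cortical_sheet`.
#' @export
cortical_sheet <- function(vertices, edges) {
  stopifnot(all(c("vertex", "hemi", "region", "x_mm", "y_mm") %in%
                  names(vertices)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(vertices) - igraph::vcount(g)))
  w <- sqrt((vertices$x_mm[edges[, 1]] - vertices$x_mm[edges[, 2]])^2 +
              (vertices$y_mm[edges[, 1]] - vertices$y_mm[edges[, 2]])^2)
  d <- igraph::distances(g, weights = w)
  structure(list(vertices = vertices, edges = edges, dist_mm = d),
            class = "cortical_sheet")
}

#' @method print cortical_sheet
#' @export
print.cortical_sheet <- function(x, ...) {
  cat(sprintf("<cortical_sheet: %d vertices, %d edges, hemis %s>\n",
              nrow(x$vertices), nrow(x$edges),
              paste(unique(x$vertices$hemi), collapse = "/")))
  invisible(x)
}

n_vertices <- function(graph) nrow(graph$vertices)
graph_distances <- function(graph) graph$dist_mm

#' Generate a ground-truth retinotopic cortical sheet
#'
#' Builds two rectangular lattice patches (left and right hemisphere), each
#' carrying a complex-log-style retinotopic template: log eccentricity maps
#' along one lattice axis and polar angle along the other, the left
#' hemisphere representing the right visual hemifield and vice versa. pRF
#' size grows linearly with eccentricity. Small seeded positional jitter
#' makes vertices non-degenerate while preserving map smoothness.
#'
#' @param n_vertices Total number of vertices (>= 10; split across
#'   hemispheres).
#' @param ecc_range Eccentricity span of the template (deg).
#' @param sigma_intercept,sigma_slope Linear size-eccentricity relation
#'   `sigma = intercept + slope * ecc` (deg).
#' @param spacing_mm Lattice spacing (mm). The default (3 mm) makes a
#'   reduced-vertex sheet subsample a cortex-sized surface rather than
#'   shrink it, preserving the number of independent smoothing patches that
#'   the real analysis averages over.
#' @param jitter_deg SD of the positional jitter (deg).
#' @param regions Region labels (default `c("V1", "V2", "V3")`): each
#'   hemisphere is split into one lattice patch per region, every patch
#'   carrying a full retinotopic template of the contralateral hemifield.
#'   Patches are disconnected in the graph, so surface smoothing never
#'   crosses an areal border.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return An object of class `ground_truth_cortex`: a list with `graph`
#'   (a [cortical_sheet()]) and `truth` (data frame `vertex`, `x`, `y`,
#'   `sigma`, `ecc`, `polar`).
#' @export
make_ground_truth <- function(n_vertices, ecc_range = c(0.5, 8.6),
                              sigma_intercept = 0.5, sigma_slope = 0.2,
                              spacing_mm = 3, jitter_deg = 0.1,
                              regions = c("V1", "V2", "V3"), seed = 1) {
  if (n_vertices < 10) stop("need at least 10 vertices")
  set.seed(seed)
  n_regions <- length(regions)
  patches <- expand.grid(region = seq_len(n_regions), hemi = 1:2)
  n_patches <- nrow(patches)
  base <- n_vertices %/% n_patches
  per_patch <- rep(base, n_patches)
  extra <- n_vertices - base * n_patches
  if (extra > 0) per_patch[seq_len(extra)] <- per_patch[seq_len(extra)] + 1L
  vert_list <- list(); truth_list <- list(); edge_list <- list()
  offset <- 0L
  for (p in seq_len(n_patches)) {
    nh <- per_patch[p]
    h <- patches$hemi[p]
    ncol_ <- max(2L, ceiling(sqrt(nh)))
    nrow_ <- max(2L, ceiling(nh / ncol_))
    idx <- seq_len(nh)
    col <- (idx - 1L) %/% nrow_  # column-major fill keeps partial grids connected
    row <- (idx - 1L) %% nrow_
    u <- if (ncol_ > 1) col / (ncol_ - 1L) else rep(0, nh)
    v <- if (nrow_ > 1) row / (nrow_ - 1L) else rep(0.5, nh)
    ecc <- exp(log(ecc_range[1]) + u * (log(ecc_range[2]) - log(ecc_range[1])))
    # left hemisphere: right hemifield (-90..90); right hemisphere: the rest
    ang <- if (h == 1) -90 + v * 180 else 90 + v * 180
    x <- ecc * cos(ang * pi / 180) + stats::rnorm(nh, 0, jitter_deg)
    y <- ecc * sin(ang * pi / 180) + stats::rnorm(nh, 0, jitter_deg)
    sigma <- sigma_intercept + sigma_slope * ecc
    vert_list[[p]] <- data.frame(
      vertex = offset + idx, hemi = c("L", "R")[h],
      region = regions[patches$region[p]],
      x_mm = col * spacing_mm + (p - 1) * 1e3, y_mm = row * spacing_mm)
    truth_list[[p]] <- data.frame(vertex = offset + idx, x = x, y = y,
                                  sigma = sigma)
    right <- idx[(idx + nrow_) <= nh]
    down <- idx[(row < nrow_ - 1L) & (idx + 1L) <= nh]
    e <- rbind(cbind(right, right + nrow_), cbind(down, down + 1L))
    edge_list[[p]] <- e + offset
    offset <- offset + nh
  }
  vertices <- do.call(rbind, vert_list)
  truth <- do.call(rbind, truth_list)
  truth$ecc <- sqrt(truth$x^2 + truth$y^2)
  truth$polar <- wrap_angle_deg(atan2(truth$y, truth$x) * 180 / pi)
  graph <- cortical_sheet(vertices, do.call(rbind, edge_list))
  structure(list(graph = graph, truth = truth, seed = seed),
            class = "ground_truth_cortex")
}

# raw T x K prediction matrix for arbitrary pRF parameter vectors
prediction_matrix <- function(x, y, sigma, apertures, hrf) {
  gx <- apertures$x; gy <- apertures$y
  gauss <- matrix(0, length(gx), length(x))
  for (k in seq_along(x)) {
    gauss[, k] <- exp(-((gx - x[k])^2 + (gy - y[k])^2) / (2 * sigma[k]^2))
  }
  mass <- colSums(gauss)
  drive <- apertures$masks %*% gauss
  ok <- mass > 1e-12
  drive[, ok] <- sweep(drive[, ok, drop = FALSE], 2, mass[ok], `/`)
  drive[, !ok] <- 0
  convolve_columns(drive, hrf)
}

#' Simulate condition-dependent BOLD time series on a ground-truth cortex
#'
#' In the `"responsive"` condition every vertex's series is its true pRF's
#' predicted time course, scaled to unit peak amplitude, plus noise; in the
#' `"silent"` condition (no stimulus-locked signal, e.g. an untreated cone
#' map) the series is the noise alone. Noise is white Gaussian with
#' SD = 1 / tsnr (tSNR = signal amplitude / noise SD), optionally AR(1).
#' The noise stream depends only on the seed, so the two conditions are
#' paired when simulated with the same seed.
#'
#' @param cortex A [make_ground_truth()] result.
#' @param apertures An [compose_run()] aperture sequence.
#' @param hrf HRF kernel.
#' @param condition `"responsive"` or `"silent"`.
#' @param tsnr Temporal signal-to-noise ratio (> 0).
#' @param seed Integer seed.
#' @param ar1 AR(1) coefficient of the noise (default 0 = white; 0.3
#'   emulates BOLD autocorrelation).
#' @return T x V numeric matrix of time series.
#' @export
simulate_bold <- function(cortex, apertures, hrf = hrf_double_gamma(),
                          condition = c("responsive", "silent"), tsnr = 50,
                          seed = 1, ar1 = 0) {
  condition <- match.arg(condition)
  if (tsnr <= 0) stop("tsnr must be positive")
  t_n <- nrow(apertures$masks)
  v_n <- nrow(cortex$truth)
  set.seed(seed)
  noise <- matrix(stats::rnorm(t_n * v_n), t_n, v_n)
  if (ar1 != 0) {
    noise <- apply(noise, 2, function(w) {
      as.numeric(stats::filter(w, ar1, method = "recursive"))
    })
    noise <- noise * sqrt(1 - ar1^2)  # restore unit marginal SD
  }
  noise <- noise / tsnr
  if (condition == "silent") return(noise)
  pred <- prediction_matrix(cortex$truth$x, cortex$truth$y,
                            cortex$truth$sigma, apertures, hrf)
  amp <- apply(abs(pred), 2, max)
  amp[amp < 1e-12] <- 1
  sweep(pred, 2, amp, `/`) + noise
}

#' Null-structure experiment
#'
#' Runs the full fit + correspondence pipeline on repeated synthetic
#' datasets in which the rod map is responsive and the cone map is (by
#' default) silent, and reports the distribution of the correspondence
#' indices. With silent cone maps this probes whether noise alone can
#' produce apparent retinotopic structure; with responsive cone maps it is
#' the positive control.
#'
#' @param n_datasets Number of seeded datasets (>= 10).
#' @param config An [analysis_config()]; its synthetic-generation settings
#'   define each dataset.
#' @param seed Top-level seed; per-dataset seeds are derived from it.
#' @param cone_condition Condition of the cone map (`"silent"` default).
#' @return A list with `results` (data frame: dataset, aic_w, cc_fl,
#'   slope, intercept, n_pairs) and `fraction_aicw_gt_half`.
#' @export
null_structure_experiment <- function(n_datasets, config = analysis_config(),
                                      seed = 1,
                                      cone_condition = c("silent",
                                                         "responsive")) {
  if (n_datasets < 10) stop("need at least 10 datasets")
  cone_condition <- match.arg(cone_condition)
  design <- build_design(config)
  rows <- vector("list", n_datasets)
  for (i in seq_len(n_datasets)) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(seed, i)
    cfg_i$cone_condition <- cone_condition
    res <- run_subject(cfg_i, design = design)
    rows[[i]] <- data.frame(dataset = i, aic_w = res$summary$aic_w,
                            cc_fl = res$summary$cc_fl,
                            slope = res$summary$slope,
                            intercept = res$summary$intercept,
                            n_pairs = res$summary$n_pairs)
  }
  results <- do.call(rbind, rows)
  list(results = results,
       fraction_aicw_gt_half = mean(results$aic_w > 0.5, na.rm = TRUE))
}
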