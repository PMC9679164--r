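#' Analysis configuration
#'
#' Collects every tunable of the end-to-end synthetic-subject analysis:
#' protocol geometry, search-grid resolution, synthetic-cortex size, noise
#' level, per-condition responsiveness, thresholds, smoothing kernels and
#' seeds. Defaults follow the mapping protocol (8.6 deg field, 348 frames,
#' R-squared threshold 0.03 with fine-stage entry at 0.05, FWHM 5 mm data /
#' 3 mm parameter smoothing, two runs averaged sample-wise).
#'
#' @param n_vertices Synthetic cortical sheet size (default 96).
#' @param tsnr Per-run temporal signal-to-noise ratio (default 50).
#' @param ar1 Noise AR(1) coefficient (default 0, white).
#' @param n_runs Runs per condition, averaged sample-wise (default 2).
#' @param rod_condition,cone_condition `"responsive"` or `"silent"`.
#' @param r2_threshold Map exclusion threshold (default 0.03; 0.05 is the
#'   stringent alternative).
#' @param r2_fine Coarse-fit threshold for the fine stage (default 0.05).
#' @param fwhm_data_mm,fwhm_params_mm Surface smoothing kernels (mm).
#' @param fine Run the fine stage (default `TRUE`).
#' @param maxit Simplex iteration cap.
#' @param grid_resolution Aperture grid resolution (px/deg, default 4).
#' @param grid_n_ecc,grid_n_angle,grid_n_sigma Coarse search grid size.
#' @param n_perm Permutations for the correlation p-value (0 = skip).
#' @param seed Top-level seed; all stage seeds derive from it.
#' @param output_dir Optional directory for CSV outputs and the run log.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(n_vertices = 96, tsnr = 50, ar1 = 0, n_runs = 2,
                            rod_condition = "responsive",
                            cone_condition = "silent",
                            r2_threshold = 0.03, r2_fine = 0.05,
                            fwhm_data_mm = 5, fwhm_params_mm = 3,
                            fine = TRUE, maxit = 500, grid_resolution = 4,
                            grid_n_ecc = 12, grid_n_angle = 24,
                            grid_n_sigma = 8, n_perm = 0, seed = 1,
                            output_dir = NULL) {
  if (r2_threshold < 0 || r2_threshold >= 1) {
    stop("r2_threshold must lie in [0, 1)")
  }
  structure(as.list(environment()), class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#' @param path YAML file whose keys match [analysis_config()] arguments.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

# deterministic per-stage seed expansion (kept below 2^31)
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stage) * 104729) %%
               2147483647) + 1L
}

#' Build the shared fitting design for a configuration
#'
#' Composes the aperture sequence, HRF and coarse search grid, and
#' precomputes the grid predictions. The design depends only on protocol
#' and grid settings, so it can be built once and shared across subjects.
#'
#' @param config An [analysis_config()].
#' @return A [prf_design()].
#' @export
build_design <- function(config = analysis_config()) {
  apertures <- compose_run(protocol_config(
    grid_resolution = config$grid_resolution))
  prf_design(apertures, hrf_double_gamma(),
             default_prf_grid(n_ecc = config$grid_n_ecc,
                              n_angle = config$grid_n_angle,
                              n_sigma = config$grid_n_sigma))
}

simulate_condition <- function(cortex, design, condition, config, base_stage) {
  runs <- lapply(seq_len(config$n_runs), function(r) {
    simulate_bold(cortex, design$apertures, design$hrf, condition,
                  tsnr = config$tsnr,
                  seed = derive_seed(config$seed, base_stage + r),
                  ar1 = config$ar1)
  })
  Reduce(`+`, runs) / length(runs)
}

#' Run the full analysis for one (synthetic) subject
#'
#' Generates a ground-truth cortical sheet, simulates the rod- and
#' cone-condition BOLD runs (averaged sample-wise), fits both pRF maps with
#' the two-stage procedure, and derives the rod-cone correspondence
#' summary, visual-field coverage maps and size-by-eccentricity profiles.
#' The rod map's bin counts serve as the reference for the profile
#' exclusion rule.
#'
#' @param config An [analysis_config()].
#' @param design Optional prebuilt [build_design()] (rebuilt if `NULL`).
#' @return A list of class `subject_result`: `rod_map`, `cone_map`,
#'   `sample` (paired angles), `summary` (one-row data frame: slope,
#'   intercept, aic_w, cc_fl, cc_p, n_pairs, mean_rod_sigma,
#'   rod_retention, cone_retention, seed), `coverage` (rod/cone),
#'   `profiles` (rod/cone), `cortex`, `config`.
#' @export
run_subject <- function(config = analysis_config(), design = NULL) {
  if (is.null(design)) design <- build_design(config)
  cortex <- make_ground_truth(config$n_vertices,
                              seed = derive_seed(config$seed, 1))
  graph <- cortex$graph
  fit_one <- function(condition, base_stage) {
    ts <- simulate_condition(cortex, design, condition, config, base_stage)
    fit_prf_map(ts, design, graph, fwhm_data_mm = config$fwhm_data_mm,
                fwhm_params_mm = config$fwhm_params_mm,
                r2_fine = config$r2_fine, fine = config$fine,
                maxit = config$maxit)
  }
  rod_map <- fit_one(config$rod_condition, 10)
  cone_map <- fit_one(config$cone_condition, 20)
  sample <- paired_angle_sample(rod_map, cone_map, config$r2_threshold)
  corr <- correspondence_result(sample, n_perm = config$n_perm,
                                seed = derive_seed(config$seed, 3))
  rod_kept <- threshold_by_r2(rod_map, config$r2_threshold)
  cone_kept <- threshold_by_r2(cone_map, config$r2_threshold)
  rod_profile <- suppressWarnings(size_ecc_profile(rod_kept))
  cone_profile <- size_ecc_profile(cone_kept,
                                   reference_counts = rod_profile$n)
  summary <- cbind(corr, data.frame(
    mean_rod_sigma = mean(rod_kept$sigma),
    rod_retention = attr(rod_kept, "retention"),
    cone_retention = attr(cone_kept, "retention"),
    seed = config$seed))
  out <- structure(list(rod_map = rod_map, cone_map = cone_map,
                        sample = sample, summary = summary,
                        coverage = list(rod = coverage_map(rod_kept),
                                        cone = coverage_map(cone_kept)),
                        profiles = list(rod = rod_profile,
                                        cone = cone_profile),
                        cortex = cortex, config = config),
                   class = "subject_result")
  if (!is.null(config$output_dir)) write_subject_result(out)
  out
}

write_subject_result <- function(result) {
  dir.create(result$config$output_dir, showWarnings = FALSE,
             recursive = TRUE)
  p <- function(f) file.path(result$config$output_dir, f)
  write_prf_map(result$rod_map, p("rod_map.csv"))
  write_prf_map(result$cone_map, p("cone_map.csv"))
  utils::write.csv(result$summary, p("summary.csv"), row.names = FALSE)
  utils::write.csv(result$profiles$rod, p("profile_rod.csv"),
                   row.names = FALSE)
  utils::write.csv(result$profiles$cone, p("profile_cone.csv"),
                   row.names = FALSE)
  write_coverage_map(result$coverage$rod, p("coverage_rod.csv"))
  write_coverage_map(result$coverage$cone, p("coverage_cone.csv"))
  writeLines(c(sprintf("retinomap %s",
                       as.character(utils::packageVersion("retinomap"))),
               sprintf("seed: %d", result$config$seed),
               sprintf("generated: %s", format(Sys.time(), "%Y-%m-%d"))),
             p("run_log.txt"))
  invisible(result)
}

#' Run a cohort and classify subjects against the normative envelope
#'
#' Runs every configuration, builds the normative (slope, intercept)
#' ellipse and CC range from the designated normative subset, and
#' classifies the remaining subjects against them.
#'
#' @param configs List of [analysis_config()] objects (one per subject).
#' @param normative_subset Integer indices of the normative subjects
#'   (>= 3).
#' @param design Optional shared design (configs must share protocol/grid
#'   settings).
#' @return A list of class `cohort_report`: `results` (per-subject summary
#'   rows with `subject` and `normative` columns), `envelope`,
#'   `classification` (per non-normative subject: inside/outside flags).
#' @export
run_cohort <- function(configs, normative_subset, design = NULL) {
  if (length(normative_subset) < 3) {
    stop("the normative subset needs at least 3 subjects")
  }
  if (is.null(design)) design <- build_design(configs[[1]])
  summaries <- lapply(configs, function(cfg) {
    run_subject(cfg, design = design)$summary
  })
  results <- do.call(rbind, summaries)
  results$subject <- seq_along(configs)
  results$normative <- results$subject %in% normative_subset
  envelope <- normative_range(results[results$normative, , drop = FALSE])
  patients <- results[!results$normative, , drop = FALSE]
  classification <- NULL
  if (nrow(patients) > 0) {
    cls <- lapply(seq_len(nrow(patients)), function(i) {
      cl <- classify_against_envelope(envelope, patients[i, ])
      data.frame(subject = patients$subject[i],
                 mahalanobis2 = cl$mahalanobis2,
                 inside_ellipse = cl$inside_ellipse,
                 inside_cc_range = cl$inside_cc_range)
    })
    classification <- do.call(rbind, cls)
  }
  structure(list(results = results, envelope = envelope,
                 classification = classification),
            class = "cohort_report")
}

#' Read a vertex-by-time series table (CSV) into a T x V matrix
#'
#' @param path CSV with one row per vertex (optionally a `vertex` id
#'   column) and one column per TR sample.
#' @return T x V numeric matrix.
#' @export
read_timeseries_csv <- function(path) {
  tab <- utils::read.csv(path)
  if ("vertex" %in% names(tab)) tab$vertex <- NULL
  t(as.matrix(tab))
}

#' Write a T x V time-series matrix as a vertex-by-time CSV
#' @param ts_mat T x V matrix.
#' @param path Output path.
#' @export
write_timeseries_csv <- function(ts_mat, path) {
  df <- as.data.frame(t(ts_mat))
  names(df) <- sprintf("t%03d", seq_len(nrow(ts_mat)))
  df <- cbind(vertex = seq_len(ncol(ts_mat)), df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a cortical sheet from vertex and edge CSV files
#' @param vertex_path CSV with `vertex`, `hemi`, `region`, `x_mm`, `y_mm`.
#' @param edge_path CSV with `from`, `to`.
#' @return A [cortical_sheet()].
#' @export
read_cortical_sheet <- function(vertex_path, edge_path) {
  v <- utils::read.csv(vertex_path)
  e <- utils::read.csv(edge_path)
  cortical_sheet(v, cbind(e$from, e$to))
}

#' Write a cortical sheet to vertex and edge CSV files
#' @param graph A [cortical_sheet()].
#' @param vertex_path,edge_path Output paths.
#' @export
write_cortical_sheet <- function(graph, vertex_path, edge_path) {
  utils::write.csv(graph$vertices, vertex_path, row.names = FALSE)
  utils::write.csv(data.frame(from = graph$edges[, 1],
                              to = graph$edges[, 2]),
                   edge_path, row.names = FALSE)
  invisible(vertex_path)
}
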