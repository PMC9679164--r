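# Shared fixtures, built once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

toy_display <- function(gamma = 1) {
  synthetic_display_model(gamma = gamma)
}

toy_receptors <- function() cached("receptors", synthetic_receptor_set())

toy_matrix <- function(gamma = 1) {
  cached(paste0("matrix", gamma),
         build_excitation_matrix(toy_display(gamma), toy_receptors()))
}

# coarse aperture sequence + small search grid reused by fitting tests
test_apertures <- function() {
  cached("apertures", compose_run(protocol_config(grid_resolution = 2)))
}

test_design <- function() {
  cached("design", prf_design(test_apertures(), hrf_double_gamma(),
                              default_prf_grid(n_ecc = 8, n_angle = 16,
                                               n_sigma = 5)))
}

# hand-built single-frame aperture over a tiny pixel grid
manual_apertures <- function(masks, x, y) {
  structure(list(masks = masks, x = x, y = y), class = "aperture_sequence")
}

# small analysis configuration for pipeline tests
test_config <- function(...) {
  analysis_config(n_vertices = 48, grid_resolution = 2, grid_n_ecc = 8,
                  grid_n_angle = 16, grid_n_sigma = 5, maxit = 250,
                  ar1 = 0.3, ...)
}
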