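# Shared fixtures, built once per test run.

.fixture_env <- new.env()

# moderate-resolution mesh for geometry/metric tests
test_mesh <- function() {
  if (is.null(.fixture_env$mesh)) {
    .fixture_env$mesh <- biv_mesh(n_theta = 32, n_z = 16)
  }
  .fixture_env$mesh
}

# default-resolution mesh (the study geometry)
default_mesh <- function() {
  if (is.null(.fixture_env$default_mesh)) {
    .fixture_env$default_mesh <- biv_mesh()
  }
  .fixture_env$default_mesh
}

# small random idealized meshes (<= ~500 vertices) for simulator oracles
random_small_mesh <- function() {
  biv_mesh(
    long_axis_mm = stats::runif(1, 70, 110),
    lv_epi_radius_mm = stats::runif(1, 28, 42),
    lv_wall_mm = stats::runif(1, 7, 12),
    rv_bulge_mm = stats::runif(1, 12, 20),
    rv_wall_mm = stats::runif(1, 3, 6),
    rv_extent = stats::runif(1, 0.7, 0.85),
    septal_half_angle_deg = stats::runif(1, 50, 70),
    n_theta = sample(c(12L, 16L), 1),
    n_z = sample(c(6L, 8L), 1)
  )
}

# scenario with explicit source vertices (bypasses named landmarks)
raw_scenario <- function(vertex_ids, onsets = 0, fast_layer = FALSE,
                         name = "test") {
  onsets <- as.list(onsets)
  sources <- lapply(seq_along(vertex_ids), function(i) {
    list(
      site = list(name = name, vertex_ids = vertex_ids[[i]]),
      onset = onsets[[min(i, length(onsets))]]
    )
  })
  structure(
    list(name = name, sources = sources, fast_layer = fast_layer),
    class = "pacing_scenario"
  )
}
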