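# shared fixtures: built once per test run, lazily

fixture_env <- new.env(parent = emptyenv())

# a small but complete ID5-pattern season used by simulator-level tests
small_season <- function() {
  if (is.null(fixture_env$small_season)) {
    w <- generate_synthetic_weather(seed = 42)
    cfg <- simulation_config(plot = c(1.7, 0.5))
    st <- season_init(5, seed = 42, config = cfg)
    for (i in seq_len(nrow(w))) st <- simulate_step(st, w[i, ])
    fixture_env$small_season <- list(state = st, weather = w, config = cfg)
  }
  fixture_env$small_season
}

# a reproducible random scene of narrow leaves for light-model tests
random_leaf_scene <- function(n_leaves = 20, seed = 7) {
  set.seed(seed)
  geoms <- lapply(seq_len(n_leaves), function(i) {
    g <- build_leaf_geometry(
      length = runif(1, 0.3, 0.5),
      area = runif(1, 0.003, 0.006),
      n_facets = 2,
      base = c(runif(1, 0.2, 0.8), runif(1, 0.2, 0.8), 0),
      azimuth = runif(1, 0, 360)
    )
    g$leaf <- i
    g
  })
  do.call(rbind, geoms)
}

# dome with a single source straight overhead
zenith_dome <- function(weight = 100) {
  d <- tibble::tibble(source = "sun", elevation = 90, azimuth = 180,
                      ux = 0, uy = 0, uz = 1, weight = weight)
  attr(d, "total_flux") <- weight
  d
}

# projection config suited to broad horizontal test facets
dense_projection <- function(cell = 0.25) {
  light_config(mode = "projection", cell_size = cell, sample_spacing = 0.01,
               tile = FALSE)
}
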