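# Shared fixtures, generated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# A small island: quick to build, still has well-populated seasonal bands.
small_island <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- generate_island(
      island_config(extent_km = 16, n_tracks = 8, rng_seed = 101L),
      make_dung_piles = FALSE)
  }
  .fixtures$small
}

# Default-condition island including the synthetic dung-pile records.
default_island <- function() {
  if (is.null(.fixtures$default)) {
    .fixtures$default <- generate_island(island_config(), make_dung_piles = TRUE)
  }
  .fixtures$default
}

# Straight-line daily track along +x with the given step (m).
line_track <- function(n_fixes, step_m = 100, id = "line") {
  tibble::tibble(
    individual_id = id,
    timestamp = as.POSIXct("2020-01-01 00:00:00", tz = "UTC") +
      (seq_len(n_fixes) - 1) * 86400,
    x = (seq_len(n_fixes) - 1) * step_m,
    y = 0,
    lon = 0, lat = 0
  )
}

# Correlated random walk track with gamma steps and normal heading noise —
# the parametric family the synthetic generator draws its tracks from.
bcrw_track <- function(n_steps, shape = 5, scale = 120, turn_sd = 0.5,
                       seed = 1, id = "bcrw") {
  withr::with_seed(seed, {
    st <- rgamma(n_steps, shape, scale = scale)
    tu <- rnorm(n_steps, 0, turn_sd)
    hd <- cumsum(tu)
    tibble::tibble(
      individual_id = id,
      timestamp = as.POSIXct("2020-01-01 00:00:00", tz = "UTC") +
        (0:n_steps) * 86400,
      x = c(0, cumsum(st * cos(hd))),
      y = c(0, cumsum(st * sin(hd))),
      lon = 0, lat = 0
    )
  })
}

# Minimal grid wrapper for dispersal unit tests: a hex grid with hand-set
# layers (guava everywhere or nowhere etc.).
flat_grid <- function(extent_km = 6, guava = FALSE, elevation = 100,
                      suitable = TRUE) {
  g <- hex_grid(extent_km, hex_area_km2 = 1.18)
  g$elevation <- elevation
  g$ndvi <- 0.5
  g$guava <- guava
  g$landcover <- "shrubland"
  g$zone <- "park"
  g$suitable <- suitable
  g
}

# Seasonal distribution built directly from cell ids and weights.
energy_dist <- function(cell_id, weight, season = "test") {
  out <- tibble::tibble(cell_id = cell_id, weight = weight)
  attr(out, "season") <- season
  attr(out, "population_size") <- sum(weight)
  class(out) <- c("seasonal_distribution", class(out))
  out
}

# Scaled-down end-to-end simulation shared by the elevation-signature and
# stop-frequency analyses: population 200, 5 repeats, trajectories shared
# across the 1/2/4 stops-per-day variants within each repeat.
dispersal_study <- function() {
  if (!is.null(.fixtures$study)) return(.fixtures$study)
  bundle <- default_island()
  grid <- bundle$grid
  kernels <- fit_bundle_kernels(bundle)
  set.seed(2024)
  rng <- seasonal_ranges_from_tracks(bundle$tracks, grid)
  H <- energy_from_ndvi(grid, rng$highland, 200)
  L <- energy_from_ndvi(grid, rng$lowland, 200)
  flow <- solve_transport(H, L, transport_cost(grid, H, L))
  asg <- assign_individuals(flow, 200)
  retention <- retention_model()
  load <- seed_load_model()

  events <- list()
  for (r in 1:5) {
    set.seed(5000 + r)
    trajs <- run_population(asg, kernels, grid)
    split_trajs <- split(trajs, trajs$individual_id)
    for (stops in c(1L, 2L, 4L)) {
      set.seed(9000 + r)  # shared seeds across stop variants
      ev <- dplyr::bind_rows(lapply(split_trajs, function(tr) {
        suppressWarnings(simulate_dispersal(
          tr, grid, retention, load, stops_per_day = stops,
          init_fraction = bundle$config$guava_highland_fraction))
      }))
      ev$repeat_id <- r
      ev$stops_per_day <- stops
      events[[length(events) + 1]] <- ev
    }
  }
  .fixtures$study <- list(bundle = bundle, ranges = rng, flow = flow,
                          assignments = asg,
                          events = dplyr::bind_rows(events))
  .fixtures$study
}
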