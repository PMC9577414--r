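#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end simulation. Defaults reproduce
#' the framework's reference settings: 1000 migrating individuals, 25
#' stochastic repeats, one stop per day, 95% utilization-distribution
#' isopleths. The configuration round-trips losslessly through JSON.
#'
#' @param population_size Number of migrating individuals.
#' @param repeats Stochastic repeats of the trajectory + dispersal stages.
#' @param stops_per_day Daily stops (1, 2 or 4).
#' @param isopleth UD isopleth for the seasonal ranges.
#' @param rng_seed Master seed; all stage substreams derive from it.
#' @param island [island_config()] for synthetic input generation.
#' @param settle_days Post-arrival residence days in the dispersal model.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(population_size = 1000, repeats = 25,
                            stops_per_day = 1, isopleth = 0.95,
                            rng_seed = 1L, island = island_config(),
                            settle_days = NULL) {
  stopifnot(population_size >= 1, repeats >= 1, stops_per_day %in% c(1, 2, 4))
  structure(
    list(population_size = population_size, repeats = repeats,
         stops_per_day = stops_per_day, isopleth = isopleth,
         rng_seed = as.integer(rng_seed), island = island,
         settle_days = settle_days),
    class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full dispersal-simulation pipeline
#'
#' Executes ranges -> connectivity -> trajectories -> dispersal -> fate ->
#' validate on a synthetic island bundle (generated from
#' `config$island` unless one is supplied), writing every artifact plus a
#' manifest to `out_dir` when given. Each stochastic repeat re-simulates the
#' population's trajectories and dispersal, as the reference procedure
#' prescribes; per-stage RNG substreams derive from the master seed, so a
#' fixed seed yields identical outputs and manifests.
#'
#' @param config A [pipeline_config()].
#' @param bundle Optional pre-built [generate_island()] bundle.
#' @param out_dir Optional output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return List with `bundle`, `ranges`, `H`, `L`, `flow`, `assignments`,
#'   `kernels`, `events`, `seed_rain`, `seed_fate`, `summaries`,
#'   `validation`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), bundle = NULL,
                         out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$rng_seed

  if (is.null(bundle)) {
    say("generating synthetic island")
    isl <- config$island
    isl$rng_seed <- substream_seed(seed, 1)
    bundle <- run_stage("synthetic", generate_island(isl))
  }
  grid <- bundle$grid

  say("estimating seasonal ranges")
  ranges <- run_stage("ranges", {
    set.seed(substream_seed(seed, 2))
    seasonal_ranges_from_tracks(bundle$tracks, grid, isopleth = config$isopleth)
  })

  say("solving migratory connectivity")
  conn <- run_stage("connectivity", {
    H <- energy_from_ndvi(grid, ranges$highland, config$population_size)
    L <- energy_from_ndvi(grid, ranges$lowland, config$population_size)
    costs <- transport_cost(grid, H, L)
    flow <- solve_transport(H, L, costs)
    list(H = H, L = L, flow = flow,
         assignments = assign_individuals(flow, config$population_size))
  })

  say("fitting movement kernels")
  kernels <- run_stage("trajectories", fit_bundle_kernels(bundle))

  retention <- retention_model()
  load <- seed_load_model()
  settle <- if (is.null(config$settle_days)) retention$max_days else config$settle_days

  say("simulating %d repeats of %d migrants", config$repeats, config$population_size)
  events <- run_stage("dispersal", {
    reps <- lapply(seq_len(config$repeats), function(r) {
      set.seed(substream_seed(seed, 100 + r))
      trajs <- run_population(conn$assignments, kernels, grid)
      trajs %>%
        group_by(.data$individual_id) %>%
        dplyr::group_map(~ simulate_dispersal(
          mutate(.x, individual_id = .y$individual_id), grid, retention, load,
          stops_per_day = config$stops_per_day, settle_days = settle,
          init_fraction = bundle$config$guava_highland_fraction)) %>%
        bind_rows() %>%
        mutate(repeat_id = r)
    })
    bind_rows(reps)
  })

  say("accumulating seed rain and fate")
  rain <- run_stage("fate", accumulate_seed_rain(events, grid))
  fate <- run_stage("fate", apply_fate_mask(rain, grid))

  say("validating against dung-pile records")
  validation <- run_stage("validate", {
    summaries <- summarize_deposition(events, grid)
    ks <- if (!is.null(bundle$dung_piles)) {
      obs <- bundle$dung_piles$elevation[bundle$dung_piles$contains_guava]
      ks_compare(obs, events$elevation)
    } else NULL
    list(summaries = summaries, ks_elevation = ks)
  })

  manifest <- list(
    package = "seedrain",
    version = as.character(utils::packageVersion("seedrain")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    rng_seed = seed,
    config_hash = object_hash(unclass(config)),
    population_size = config$population_size,
    repeats = config$repeats,
    stops_per_day = config$stops_per_day,
    n_cells = nrow(grid),
    n_events = nrow(events),
    total_seeds = sum(events$seeds),
    crs = "local equirectangular tangent plane, metres",
    origin_lonlat = attr(grid, "origin_lonlat")
  )

  result <- list(bundle = bundle, ranges = ranges, H = conn$H, L = conn$L,
                 flow = conn$flow, assignments = conn$assignments,
                 kernels = kernels, events = events, seed_rain = rain,
                 seed_fate = fate, summaries = validation$summaries,
                 validation = validation$ks_elevation, manifest = manifest)
  if (!is.null(out_dir)) write_run(result, out_dir)
  result
}

#' Estimate highland and lowland seasonal ranges from labelled tracks
#'
#' Splits fixes into highland/lowland subsets (by `phase` label when
#' present, otherwise by elevation relative to the midpoint of the grid's
#' range), estimates a per-individual UD for each subset, and converts the
#' pooled UDs into population ranges on the grid.
#'
#' @param tracks Track tibble.
#' @param grid A `hex_grid` with `elevation`.
#' @param isopleth UD isopleth.
#' @return List with `highland` and `lowland` [seasonal_range()]s.
#' @export
seasonal_ranges_from_tracks <- function(tracks, grid, isopleth = 0.95) {
  tracks <- project_tracks(tracks)
  if ("phase" %in% names(tracks)) {
    hi <- tracks %>% filter(.data$phase == "highland_residency")
    lo <- tracks %>% filter(.data$phase == "lowland_residency")
  } else {
    elev <- grid$elevation[match(cells_at(grid, tracks$x, tracks$y), grid$cell_id)]
    mid <- mean(range(grid$elevation))
    hi <- tracks[which(elev >= mid), ]
    lo <- tracks[which(elev < mid), ]
  }
  ud_set <- function(sub) {
    ids <- unique(sub$individual_id)
    lapply(ids, function(id) {
      suppressWarnings(estimate_ud(sub %>% filter(.data$individual_id == id),
                                   isopleth = isopleth))
    })
  }
  list(
    highland = seasonal_range(ud_set(hi), grid, season = "highland"),
    lowland = seasonal_range(ud_set(lo), grid, season = "lowland")
  )
}

# ---- artifact writers (plain-text formats: CSV + GeoJSON + JSON) ----

geojson_fc <- function(features) {
  list(type = "FeatureCollection",
       crs = list(type = "name",
                  properties = list(name = "local-tangent-plane-metres")),
       features = features)
}

geojson_polygon_feature <- function(poly, properties = list()) {
  rings <- lapply(split(poly, poly$ring), function(rg) {
    coords <- cbind(rg$x, rg$y)
    rbind(coords, coords[1, , drop = FALSE])
  })
  list(type = "Feature", properties = properties,
       geometry = list(type = "Polygon", coordinates = rings))
}

geojson_line_feature <- function(x, y, properties = list()) {
  list(type = "Feature", properties = properties,
       geometry = list(type = "LineString", coordinates = cbind(x, y)))
}

write_geojson <- function(fc, path) {
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 8)
}

#' Write all pipeline artifacts to a directory
#'
#' @param result A [run_pipeline()] result list.
#' @param out_dir Target directory.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  grid <- result$bundle$grid

  write.csv(as.data.frame(grid), p("grid_layers.csv"), row.names = FALSE)
  write.csv(as.data.frame(result$bundle$tracks), p("tracks.csv"), row.names = FALSE)
  if (!is.null(result$bundle$dung_piles)) {
    write.csv(as.data.frame(result$bundle$dung_piles), p("dung_piles.csv"),
              row.names = FALSE)
  }
  write.csv(as.data.frame(result$flow), p("flows.csv"), row.names = FALSE)
  write.csv(as.data.frame(result$assignments), p("assignments.csv"), row.names = FALSE)
  write.csv(as.data.frame(result$events), p("events.csv"), row.names = FALSE)
  write.csv(as.data.frame(result$seed_rain), p("seed_rain.csv"), row.names = FALSE)
  write.csv(as.data.frame(result$seed_fate), p("seed_fate.csv"), row.names = FALSE)

  write_geojson(geojson_fc(list(
    geojson_polygon_feature(result$ranges$highland$hull,
                            list(season = "highland")),
    geojson_polygon_feature(result$ranges$lowland$hull,
                            list(season = "lowland"))
  )), p("ranges.geojson"))

  if (!is.null(result$validation)) {
    jsonlite::write_json(
      list(ks_elevation = as.list(result$validation),
           by_zone = result$summaries$by_zone,
           by_landcover = result$summaries$by_landcover),
      p("validation.json"), auto_unbox = TRUE, digits = 10)
  }
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(out_dir)
}
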