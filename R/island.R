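#' Configuration for the synthetic island generator
#'
#' Describes a self-contained volcanic-island study system: a radial
#' elevation gradient, a highland seasonal range around the summit and a
#' lowland coastal range in the migration sector, source-plant patches
#' covering a set fraction of the highland, and downslope migration tracks.
#' Defaults give an island whose structure matches the assumptions of the
#' dispersal pipeline: ~1.18 km^2 hexagonal cells and source plants on 21%
#' of the highland range.
#'
#' @param extent_km Width/height of the square domain (km).
#' @param hex_area_km2 Target hexagon area (km^2).
#' @param elevation_peak_m Summit elevation (m).
#' @param highland_band_m,lowland_band_m Elevation bands `c(lo, hi)` (m)
#'   defining the seasonal ranges; must not overlap.
#' @param guava_highland_fraction Fraction of highland cells carrying the
#'   source plant.
#' @param n_tracks Number of synthetic migration tracks.
#' @param rng_seed Integer seed; fixed seed implies byte-identical bundles.
#' @param step_shape,step_scale Gamma parameters of daily migration step
#'   lengths (m).
#' @param turn_sd Wrapped-normal sd of heading noise (rad).
#' @param bias_weight Weight of the pull toward the migration target when
#'   mixing with the previous heading (0 = pure correlated walk).
#' @param residency_days_highland,residency_days_lowland Days of localized
#'   wandering before/after the migration leg (these provide the fixes from
#'   which seasonal utilization distributions are estimated).
#' @param sector_halfwidth_rad Angular half-width of the lowland migration
#'   sector (centred due south of the summit).
#' @return A list of class `island_config`.
#' @export
island_config <- function(extent_km = 24,
                          hex_area_km2 = 1.18,
                          elevation_peak_m = 860,
                          highland_band_m = c(250, 450),
                          lowland_band_m = c(0, 150),
                          guava_highland_fraction = 0.21,
                          n_tracks = 17,
                          rng_seed = 42L,
                          step_shape = 5,
                          step_scale = 80,
                          turn_sd = 0.5,
                          bias_weight = 0.4,
                          residency_days_highland = 35,
                          residency_days_lowland = 32,
                          sector_halfwidth_rad = 0.55) {
  stopifnot(
    extent_km > 0, hex_area_km2 > 0, elevation_peak_m > 0,
    guava_highland_fraction >= 0, guava_highland_fraction <= 1,
    length(highland_band_m) == 2, length(lowland_band_m) == 2,
    n_tracks >= 1
  )
  if (max(lowland_band_m) > min(highland_band_m)) {
    abort("elevation bands must not overlap")
  }
  structure(as.list(environment()), class = "island_config")
}

#' Generate a synthetic island study system
#'
#' Builds the full input bundle the dispersal pipeline expects: a hex grid
#' carrying elevation (a radial cone from the island centre, so elevation
#' decreases monotonically in expectation outward), NDVI (decreasing with
#' elevation plus noise, i.e. greener lowlands), source-plant presence on
#' the configured fraction of highland cells, elevation-banded landcover and
#' park/agricultural zoning, a binary establishment-suitability mask,
#' migration tracks (downslope-biased correlated random walks with gamma
#' step lengths and serially correlated headings, bracketed by highland and
#' lowland residency phases), and — optionally — a synthetic "observed"
#' dung-pile data set produced by running the dispersal simulator once on a
#' small population and subsampling.
#'
#' @param config An [island_config()].
#' @param make_dung_piles Generate the synthetic dung-pile records (runs a
#'   small internal simulation; disable for speed when not needed).
#' @return A list of class `island_bundle`: `grid`, `tracks`, `dung_piles`,
#'   `highland_cells`, `lowland_cells`, `track_params`, `config`.
#' @export
generate_island <- function(config = island_config(), make_dung_piles = TRUE) {
  stopifnot(inherits(config, "island_config"))
  set.seed(config$rng_seed)
  grid <- hex_grid(config$extent_km, config$hex_area_km2)
  ext <- attr(grid, "extent_m")
  cx <- ext / 2; cy <- ext / 2
  rr <- sqrt((grid$x - cx)^2 + (grid$y - cy)^2)

  # concave shield-volcano profile: steep near the summit, long gentle
  # coastal apron (exponent 1.3), plus small topographic noise
  grid$elevation <- pmax(
    config$elevation_peak_m * pmax(0, 1 - rr / (ext / 2))^1.3 +
      rnorm(nrow(grid), 0, 5),
    0)
  grid$ndvi <- pmin(pmax(
    0.85 - 0.55 * grid$elevation / config$elevation_peak_m +
      rnorm(nrow(grid), 0, 0.04), 0.05), 1)

  hb <- config$highland_band_m; lb <- config$lowland_band_m
  on_island <- rr <= ext / 2  # beyond the cone base lies the coastal fringe
  in_high <- grid$elevation >= hb[1] & grid$elevation <= hb[2] & on_island
  in_low <- grid$elevation >= lb[1] & grid$elevation <= lb[2] & on_island
  if (!any(in_high)) abort("degenerate domain: no cells in the highland band")
  if (!any(in_low)) abort("degenerate domain: no cells in the lowland band")

  # Seasonal ranges are convex-hull fills (the population-range construction
  # downstream is also a convex hull, so the truth regions are convex):
  # the highland range fills the belt around the summit; the lowland range
  # fills the coastal sector due south of the summit. Track endpoints and
  # source plants stay confined to the underlying elevation-band cells.
  hull_fill <- function(idx) {
    h <- chull(grid$x[idx], grid$y[idx])
    hull <- tibble(ring = 1L, x = grid$x[idx][h], y = grid$y[idx][h])
    grid$cell_id[points_in_polygon(grid$x, grid$y, hull) |
                   seq_len(nrow(grid)) %in% idx]
  }
  # both seasonal ranges occupy the southern flank (the migratory part of
  # the population lives on one side of the volcano, not around it); the
  # highland arc is somewhat wider than the lowland sector
  ang <- atan2(grid$y - cy, grid$x - cx)
  lo_sector <- abs(wrap_angle(ang - (-pi / 2))) <= config$sector_halfwidth_rad
  hi_sector <- abs(wrap_angle(ang - (-pi / 2))) <=
    min(pi, config$sector_halfwidth_rad + 0.35)
  sect <- which(in_low & lo_sector)
  hsect <- which(in_high & hi_sector)
  if (length(sect) < 3) abort("degenerate domain: lowland migration sector empty")
  if (length(hsect) < 3) abort("degenerate domain: highland range sector empty")
  highland_band_cells <- grid$cell_id[hsect]
  lowland_band_cells <- grid$cell_id[sect]
  highland_cells <- hull_fill(hsect)
  lowland_cells <- hull_fill(sect)

  grid$guava <- FALSE
  n_guava <- min(round(config$guava_highland_fraction * length(highland_cells)),
                 length(highland_band_cells))
  if (n_guava > 0) {
    grid$guava[match(sample(highland_band_cells, n_guava), grid$cell_id)] <- TRUE
  }

  grid$landcover <- cut(
    grid$elevation, c(-Inf, lb[2], hb[1], 450, Inf),
    labels = c("shrubland", "transition_forest", "agriculture", "fern_sedge"))
  grid$landcover <- as.character(grid$landcover)
  grid$zone <- ifelse(grid$elevation >= hb[1] & grid$elevation <= 450,
                      "agricultural", "park")
  grid$suitable <- grid$elevation >= 50 & grid$elevation <= 350

  tracks <- generate_tracks(grid, config, highland_band_cells,
                            lowland_band_cells, highland_cells, lowland_cells)

  track_params <- list(
    step_shape = config$step_shape, step_scale = config$step_scale,
    turn_sd = config$turn_sd, bias_weight = config$bias_weight,
    residency_step_shape = 3,
    residency_step_scale = c(highland = 80, lowland = 80)
  )

  bundle <- structure(
    list(grid = grid, tracks = tracks, dung_piles = NULL,
         highland_cells = highland_cells, lowland_cells = lowland_cells,
         highland_band_cells = highland_band_cells,
         lowland_band_cells = lowland_band_cells,
         track_params = track_params, config = config),
    class = "island_bundle")

  if (make_dung_piles) {
    bundle$dung_piles <- synth_dung_piles(bundle)
  }
  bundle
}

# Downslope-biased correlated random walk with residency phases at both
# ends. Headings mix the previous heading with the bearing to the target
# (weight `bias_weight`) plus wrapped-normal noise; steps are gamma.
generate_tracks <- function(grid, config, start_pool, dest_pool,
                            highland_cells, lowland_cells) {
  origin <- attr(grid, "origin_lonlat")
  out <- vector("list", config$n_tracks)
  t0 <- as.POSIXct("2015-06-01 12:00:00", tz = "UTC")

  # residency sites stratified by bearing around the summit, mirroring how
  # tracked individuals are tagged across a population's whole range
  ext <- attr(grid, "extent_m")
  strat <- function(pool, n) {
    gi <- match(pool, grid$cell_id)
    ord <- pool[order(atan2(grid$y[gi] - ext / 2, grid$x[gi] - ext / 2))]
    idx <- pmin(length(ord),
                1 + floor((seq_len(n) - runif(n)) / n * length(ord)))
    ord[idx]
  }
  starts <- strat(start_pool, config$n_tracks)
  dests <- strat(dest_pool, config$n_tracks)
  # migrations shorter than ~5.5 km give too few daily fixes to characterize
  # movement; re-pair such starts with the nearest destination beyond that
  dist_cells <- function(a, b) {
    ai <- match(a, grid$cell_id); bi <- match(b, grid$cell_id)
    sqrt((grid$x[ai] - grid$x[bi])^2 + (grid$y[ai] - grid$y[bi])^2)
  }
  for (i in seq_len(config$n_tracks)) {
    if (dist_cells(starts[i], dests[i]) < 5500) {
      dd <- dist_cells(rep(starts[i], length(dest_pool)), dest_pool)
      far <- dest_pool[dd >= 5500]
      dests[i] <- if (length(far)) far[which.min(dd[dd >= 5500])]
                  else dest_pool[which.max(dd)]
    }
  }

  for (i in seq_len(config$n_tracks)) {
    start_cell <- starts[i]
    dest_cell <- dests[i]
    si <- match(start_cell, grid$cell_id); di <- match(dest_cell, grid$cell_id)
    p <- c(grid$x[si], grid$y[si]); target <- c(grid$x[di], grid$y[di])

    # localized residency walk, confined to the seasonal range: steps that
    # would exit the range are redirected toward the anchor site
    wander <- function(p, anchor, days, scale, allowed) {
      xs <- numeric(days); ys <- numeric(days)
      headv <- runif(1, -pi, pi)
      for (d in seq_len(days)) {
        st <- rgamma(1, 3, scale = scale)
        to_anchor <- atan2(anchor[2] - p[2], anchor[1] - p[1])
        v <- 0.5 * c(cos(headv), sin(headv)) + 0.5 * c(cos(to_anchor), sin(to_anchor))
        headv <- atan2(v[2], v[1]) + rnorm(1, 0, 0.8)
        cand <- p + st * c(cos(headv), sin(headv))
        cc <- cells_at(grid, cand[1], cand[2])
        if (is.na(cc) || !(cc %in% allowed)) {
          headv <- to_anchor
          cand <- p + st * c(cos(headv), sin(headv))
        }
        p <- cand
        xs[d] <- p[1]; ys[d] <- p[2]
      }
      list(p = p, x = xs, y = ys)
    }

    res_h <- wander(p, p, config$residency_days_highland, scale = 80,
                    allowed = highland_cells)
    p <- res_h$p

    mig_x <- numeric(0); mig_y <- numeric(0)
    headv <- atan2(target[2] - p[2], target[1] - p[1])
    for (d in seq_len(120)) {
      st <- rgamma(1, config$step_shape, scale = config$step_scale)
      bearing <- atan2(target[2] - p[2], target[1] - p[1])
      w <- config$bias_weight
      v <- (1 - w) * c(cos(headv), sin(headv)) + w * c(cos(bearing), sin(bearing))
      headv <- atan2(v[2], v[1]) + rnorm(1, 0, config$turn_sd)
      p <- p + st * c(cos(headv), sin(headv))
      mig_x <- c(mig_x, p[1]); mig_y <- c(mig_y, p[2])
      if (sqrt(sum((p - target)^2)) < 800) break
    }

    res_l <- wander(p, target, config$residency_days_lowland, scale = 80,
                    allowed = lowland_cells)
    # guarantee the final fix sits in a lowland cell
    res_l$x[length(res_l$x)] <- target[1]
    res_l$y[length(res_l$y)] <- target[2]

    xs <- c(grid$x[si], res_h$x, mig_x, res_l$x)
    ys <- c(grid$y[si], res_h$y, mig_y, res_l$y)
    phase <- c("highland_residency",
               rep("highland_residency", length(res_h$x)),
               rep("migration", length(mig_x)),
               rep("lowland_residency", length(res_l$x)))
    ll <- xy_to_lonlat(xs, ys, origin)
    out[[i]] <- tibble(
      individual_id = sprintf("trk_%02d", i),
      timestamp = t0 + (seq_along(xs) - 1) * 86400,
      lon = ll$lon, lat = ll$lat,
      x = xs, y = ys, phase = phase,
      start_cell = start_cell, dest_cell = dest_cell
    )
  }
  bind_rows(out)
}

# One small dispersal run at the bundle's seed state, subsampled into an
# "observed" dung-pile data set (synthetic throughout: piles that contain
# the source plant come from simulated excretion events, the rest from
# excretion-free daily stops).
synth_dung_piles <- function(bundle, n_guava_piles = 101, n_plain_piles = 121,
                             population = 40) {
  grid <- bundle$grid
  kernels <- fit_bundle_kernels(bundle)
  H <- energy_tibble(grid, bundle$highland_cells, population)
  L <- energy_tibble(grid, bundle$lowland_cells, population)
  costs <- transport_cost(grid, H, L)
  flow <- solve_transport(H, L, costs)
  asg <- assign_individuals(flow, population)
  trajs <- run_population(asg, kernels, grid)
  retention <- retention_model()
  load <- seed_load_model()
  events <- trajs %>%
    group_by(.data$individual_id) %>%
    dplyr::group_map(~ simulate_dispersal(
      mutate(.x, individual_id = .y$individual_id), grid,
      retention, load,
      init_fraction = bundle$config$guava_highland_fraction)) %>%
    bind_rows()

  guava_piles <- events %>%
    slice(sample(n(), min(n_guava_piles, n()))) %>%
    mutate(contains_guava = TRUE) %>%
    select("x", "y", "elevation", "cell_id", "contains_guava")

  stops <- trajs %>%
    filter(.data$step > 0) %>%
    mutate(cell_id = cells_at(grid, .data$x, .data$y)) %>%
    filter(!is.na(.data$cell_id)) %>%
    slice(sample(n(), min(n_plain_piles, n()))) %>%
    mutate(elevation = grid$elevation[match(.data$cell_id, grid$cell_id)],
           contains_guava = FALSE) %>%
    select("x", "y", "elevation", "cell_id", "contains_guava")

  origin <- attr(grid, "origin_lonlat")
  piles <- bind_rows(guava_piles, stops)
  ll <- xy_to_lonlat(piles$x, piles$y, origin)
  piles %>%
    mutate(lon = ll$lon, lat = ll$lat,
           landcover = grid$landcover[match(.data$cell_id, grid$cell_id)],
           zone = grid$zone[match(.data$cell_id, grid$cell_id)],
           source = "observed")
}

# weights proportional to NDVI x area over an explicit cell set
energy_tibble <- function(grid, cells, population_size) {
  rng <- structure(list(season = "band", member_cells = cells,
                        hull = NULL), class = "seasonal_range")
  energy_from_ndvi(grid, rng, population_size)
}

#' Fit movement kernels for every track in a bundle
#'
#' Uses each track's migration phase (falling back to the whole track when
#' the migration leg is shorter than the 10-step minimum).
#'
#' @param bundle An `island_bundle` (or any object with a `tracks` tibble
#'   carrying `individual_id`, `x`, `y` and optionally `phase`).
#' @return List of `movement_kernel`s, one per individual.
#' @export
fit_bundle_kernels <- function(bundle) {
  tracks <- if (inherits(bundle, "island_bundle")) bundle$tracks else bundle
  ids <- unique(tracks$individual_id)
  lapply(ids, function(id) {
    tr <- tracks %>% filter(.data$individual_id == id)
    if ("phase" %in% names(tr)) {
      mig <- tr %>% filter(.data$phase == "migration")
      if (nrow(mig) >= 11) tr <- mig
    }
    fit_movement_kernel(tr)
  })
}

#' @export
print.island_bundle <- function(x, ...) {
  cat(sprintf(
    "Synthetic island: %d cells (%d highland, %d lowland), %d tracks, %s dung piles\n",
    nrow(x$grid), length(x$highland_cells), length(x$lowland_cells),
    length(unique(x$tracks$individual_id)),
    if (is.null(x$dung_piles)) "no" else nrow(x$dung_piles)))
  invisible(x)
}
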