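#' Simulate foraging, gut retention and seed excretion along a trajectory
#'
#' Walks a simulated (or observed) daily trajectory and applies the daily
#' foraging/excretion rules: the individual relocates once per day and stops
#' at `stops_per_day` locations interpolated along that day's displacement.
#' At each stop it (a) feeds on the source plant if the containing grid cell
#' holds it, setting that day's feeding flag, and (b) excretes seeds with
#' probability `P_g` computed from the gut-retention model and the feeding
#' history of the preceding `max_days` days; an excretion event deposits a
#' seed count drawn from the load model. The feeding history advances once
#' per calendar day (feeding at any stop sets the day's flag; excretion does
#' not clear the history). After arrival the individual remains at the
#' destination for `settle_days` further days under the same daily rules, so
#' seeds ingested late in the migration can still be deposited.
#'
#' @param traj Trajectory tibble with `step`, `x`, `y` (daily positions;
#'   step 0 = origin) for a single individual.
#' @param grid A `hex_grid` with `guava` (logical source-plant presence) and
#'   `elevation` columns.
#' @param retention A [retention_model()].
#' @param load A [seed_load_model()].
#' @param stops_per_day One of 1, 2, 4.
#' @param settle_days Days spent at the destination after arrival (default:
#'   the retention horizon, so the gut can empty).
#' @param history Initial feeding history (length `retention$max_days`);
#'   default drawn by [init_history()] with `init_fraction`.
#' @param init_fraction Feeding probability for the default initial history.
#' @return Tibble of excretion events: `individual_id`, `day`, `stop`,
#'   `x`, `y`, `cell_id`, `seeds`, `elevation`.
#' @export
simulate_dispersal <- function(traj, grid, retention, load,
                               stops_per_day = 1, settle_days = retention$max_days,
                               history = NULL, init_fraction = 0.21) {
  stopifnot(stops_per_day %in% c(1, 2, 4))
  if (!all(c("guava", "elevation") %in% names(grid))) {
    abort("grid needs `guava` and `elevation` layers")
  }
  if (is.null(history)) history <- init_history(init_fraction, retention$max_days)
  stopifnot(length(history) == retention$max_days)
  id <- if ("individual_id" %in% names(traj)) traj$individual_id[1] else "ind"
  traj <- traj[order(traj$step), ]
  n_days <- nrow(traj) - 1
  frac <- seq_len(stops_per_day) / stops_per_day
  Rsum <- sum(retention$R)

  events <- list()
  warn_off_grid <- FALSE
  total_days <- n_days + settle_days
  for (day in seq_len(total_days)) {
    if (day <= n_days) {
      p0 <- c(traj$x[day], traj$y[day])
      p1 <- c(traj$x[day + 1], traj$y[day + 1])
      sx <- p0[1] + (p1[1] - p0[1]) * frac
      sy <- p0[2] + (p1[2] - p0[2]) * frac
    } else {
      sx <- rep(traj$x[n_days + 1], stops_per_day)
      sy <- rep(traj$y[n_days + 1], stops_per_day)
    }
    cells <- cells_at(grid, sx, sy)
    if (anyNA(cells)) {
      warn_off_grid <- TRUE
      keep <- !is.na(cells)
    } else keep <- rep(TRUE, stops_per_day)

    gi <- match(cells[keep], grid$cell_id)
    fed_today <- any(grid$guava[gi])
    pg <- sum(retention$R * history) / Rsum
    if (pg > 0 && any(keep)) {
      excrete <- runif(sum(keep)) < pg
      if (any(excrete)) {
        widx <- which(keep)[excrete]
        events[[length(events) + 1]] <- tibble(
          individual_id = id,
          day = day,
          stop = widx,
          x = sx[widx], y = sy[widx],
          cell_id = cells[widx],
          seeds = sample_seed_count(load, length(widx)),
          elevation = grid$elevation[match(cells[widx], grid$cell_id)]
        )
      }
    }
    history <- c(as.integer(isTRUE(fed_today)), history[-retention$max_days])
  }
  if (warn_off_grid) warn("trajectory left the grid; off-grid stops skipped")
  if (length(events) == 0) {
    return(tibble(individual_id = character(), day = integer(), stop = integer(),
                  x = numeric(), y = numeric(), cell_id = integer(),
                  seeds = integer(), elevation = numeric()))
  }
  bind_rows(events)
}

#' Accumulate excretion events into a seed-rain surface
#'
#' Sums deposited seeds per grid cell, keeping per-repeat layers so the
#' stochastic envelope across simulation repeats is preserved.
#'
#' @param events Event tibble from [simulate_dispersal()], optionally with a
#'   `repeat_id` column distinguishing simulation repeats.
#' @param grid A `hex_grid`.
#' @return Object of class `seed_rain`: tibble with one row per grid cell
#'   (`cell_id`, `total_seeds`, `n_events`, `seeds_per_km2`); attributes
#'   `per_repeat` (cell x repeat totals) and `n_simulations`.
#' @export
accumulate_seed_rain <- function(events, grid) {
  if (!"repeat_id" %in% names(events)) events$repeat_id <- 1L
  per_rep <- events %>%
    group_by(.data$cell_id, .data$repeat_id) %>%
    summarise(seeds = sum(.data$seeds), n_events = n(), .groups = "drop")
  totals <- per_rep %>%
    group_by(.data$cell_id) %>%
    summarise(total_seeds = sum(.data$seeds), n_events = sum(.data$n_events),
              .groups = "drop")
  out <- tibble(cell_id = grid$cell_id) %>%
    left_join(totals, by = "cell_id") %>%
    mutate(total_seeds = dplyr::coalesce(.data$total_seeds, 0),
           n_events = dplyr::coalesce(.data$n_events, 0L),
           seeds_per_km2 = .data$total_seeds / grid$area_km2)
  attr(out, "per_repeat") <- per_rep
  attr(out, "n_simulations") <- length(unique(events$repeat_id))
  class(out) <- c("seed_rain", class(out))
  out
}

#' @export
print.seed_rain <- function(x, ...) {
  cat(sprintf(
    "Seed rain: %.0f seeds in %d events over %d occupied cells (%d repeats)\n",
    sum(x$total_seeds), sum(x$n_events), sum(x$total_seeds > 0),
    attr(x, "n_simulations")))
  invisible(x)
}
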