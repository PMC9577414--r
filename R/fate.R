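#' Convert seed rain to seed fate through the establishment mask
#'
#' Seed fate is the seed rain restricted to cells where the binary species
#' distribution model mask predicts establishment success: an elementwise
#' product of the rain surface with the `suitable` layer.
#'
#' @param rain A `seed_rain`.
#' @param grid A `hex_grid` with a logical `suitable` column.
#' @return Tibble with `cell_id`, `suitable`, `fate_seeds`,
#'   `fate_seeds_per_km2`.
#' @export
apply_fate_mask <- function(rain, grid) {
  if (!"suitable" %in% names(grid)) abort("grid has no `suitable` layer")
  gi <- match(rain$cell_id, grid$cell_id)
  if (anyNA(gi)) abort("seed rain references cells missing from the grid")
  tibble(
    cell_id = rain$cell_id,
    suitable = grid$suitable[gi],
    fate_seeds = rain$total_seeds * as.numeric(grid$suitable[gi]),
    fate_seeds_per_km2 = rain$seeds_per_km2 * as.numeric(grid$suitable[gi])
  )
}

#' Summarize seed deposition by landcover, zone and elevation
#'
#' @param events Excretion-event tibble (needs `cell_id`, `elevation`, and
#'   optionally `repeat_id`).
#' @param grid A `hex_grid` with `landcover` and `zone` columns.
#' @param elevation_breaks Breaks for the elevation histogram (metres);
#'   default 50 m bins spanning the grid.
#' @return List of tibbles: `by_landcover`, `by_zone` (counts and
#'   fractions), `by_elevation` (per-repeat bin frequencies and densities).
#' @export
summarize_deposition <- function(events, grid, elevation_breaks = NULL) {
  if (nrow(events) == 0) {
    warn("no excretion events to summarize")
    return(list(by_landcover = tibble(), by_zone = tibble(),
                by_elevation = tibble()))
  }
  if (!"repeat_id" %in% names(events)) events$repeat_id <- 1L
  gi <- match(events$cell_id, grid$cell_id)
  ev <- events %>%
    mutate(landcover = grid$landcover[gi], zone = grid$zone[gi])

  by_landcover <- ev %>%
    count(.data$landcover, name = "n_events") %>%
    mutate(fraction = .data$n_events / sum(.data$n_events))
  by_zone <- ev %>%
    count(.data$zone, name = "n_events") %>%
    mutate(fraction = .data$n_events / sum(.data$n_events))

  if (is.null(elevation_breaks)) {
    top <- max(c(ev$elevation, grid$elevation), na.rm = TRUE)
    elevation_breaks <- seq(0, ceiling(top / 50) * 50 + 50, by = 50)
  }
  by_elevation <- ev %>%
    mutate(bin = cut(.data$elevation, elevation_breaks,
                     include.lowest = TRUE, right = FALSE)) %>%
    count(.data$repeat_id, .data$bin, name = "n_events") %>%
    group_by(.data$repeat_id) %>%
    mutate(frequency = .data$n_events / sum(.data$n_events),
           density = .data$frequency / diff(elevation_breaks)[as.integer(.data$bin)]) %>%
    ungroup()

  list(by_landcover = by_landcover, by_zone = by_zone,
       by_elevation = by_elevation)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Computes the sup-norm distance between the two empirical CDFs (evaluated
#' exactly at every jump point) and the asymptotic two-sample p-value from
#' the Kolmogorov distribution.
#'
#' @param sample_a,sample_b Numeric samples (each of size >= 5), e.g.
#'   elevations of observed vs simulated dung piles.
#' @return One-row tibble of class `ks_result`: `statistic` (D), `p.value`,
#'   `n1`, `n2`.
#' @export
ks_compare <- function(sample_a, sample_b) {
  n1 <- length(sample_a); n2 <- length(sample_b)
  if (n1 < 5 || n2 < 5) abort("both samples must have at least 5 observations")
  w <- sort(unique(c(sample_a, sample_b)))
  Fa <- findInterval(w, sort(sample_a)) / n1
  Fb <- findInterval(w, sort(sample_b)) / n2
  D <- max(abs(Fa - Fb))
  ne <- n1 * n2 / (n1 + n2)
  lambda <- sqrt(ne) * D
  k <- 1:100
  if (lambda < 1) {
    # Jacobi-theta form, numerically stable for small lambda
    p <- 1 - sqrt(2 * pi) / max(lambda, 1e-12) *
      sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * max(lambda, 1e-12)^2)))
  } else {
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  out <- tibble(statistic = D, p.value = p, n1 = n1, n2 = n2)
  class(out) <- c("ks_result", class(out))
  out
}

#' Sensitivity of deposition to daily stop frequency
#'
#' Pairwise KS comparison of event elevation distributions across runs that
#' differ only in `stops_per_day`; near-zero D values indicate the
#' within-day stop interpolation does not change where seeds land.
#'
#' @param events Event tibble with a `stops_per_day` column pooling all
#'   repeats per stop frequency.
#' @return Tibble with one row per group pair: `group_a`, `group_b`,
#'   `statistic`, `p.value`, `n1`, `n2`.
#' @export
stop_sensitivity <- function(events) {
  if (!"stops_per_day" %in% names(events)) {
    abort("`events` needs a `stops_per_day` column")
  }
  groups <- sort(unique(events$stops_per_day))
  if (length(groups) < 2) abort("need at least two stop-frequency groups")
  pairs <- utils::combn(groups, 2)
  bind_rows(lapply(seq_len(ncol(pairs)), function(k) {
    a <- events$elevation[events$stops_per_day == pairs[1, k]]
    b <- events$elevation[events$stops_per_day == pairs[2, k]]
    ks_compare(a, b) %>%
      mutate(group_a = pairs[1, k], group_b = pairs[2, k], .before = 1)
  }))
}
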