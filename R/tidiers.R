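#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_polygon geom_path geom_line
#'   geom_col scale_fill_viridis_c coord_equal labs theme_minimal
#' @export
ggplot2::autoplot

#' Tidy the daily gut-retention probabilities
#' @param x A [retention_model()].
#' @param ... Unused.
#' @return Tibble with `day`, `probability`.
#' @export
tidy.retention_model <- function(x, ...) {
  tibble(day = seq_len(x$max_days), probability = x$R)
}

#' @rdname tidy.retention_model
#' @export
glance.retention_model <- function(x, ...) {
  tibble(mean_days = x$mean_days, sd_days = x$sd_days, skew = x$skew,
         max_days = x$max_days, total_mass = sum(x$R),
         mode_day = which.max(x$R))
}

#' Tidy an optimal-transport flow matrix
#' @param x A `flow_matrix`.
#' @param ... Unused.
#' @return Tibble of positive flows (`origin_cell`, `dest_cell`, `flow`).
#' @export
tidy.flow_matrix <- function(x, ...) {
  tibble(origin_cell = x$origin_cell, dest_cell = x$dest_cell, flow = x$flow)
}

#' @rdname tidy.flow_matrix
#' @export
glance.flow_matrix <- function(x, ...) {
  tibble(n_routes = nrow(x), total_flow = attr(x, "total_flow"),
         total_cost = attr(x, "total_cost"),
         mean_distance_km = attr(x, "total_cost") / attr(x, "total_flow"))
}

#' Tidy a movement kernel's binned step-length distribution
#' @param x A `movement_kernel`.
#' @param ... Unused.
#' @return Tibble with `quantity`, `bin_mid`, `probability`.
#' @export
tidy.movement_kernel <- function(x, ...) {
  smid <- (head(x$step_breaks, -1) + tail(x$step_breaks, -1)) / 2
  tmid <- (head(x$turn_breaks, -1) + tail(x$turn_breaks, -1)) / 2
  bind_rows(
    tibble(quantity = "step_m", bin_mid = smid, probability = x$step_prob),
    tibble(quantity = "turn_rad", bin_mid = tmid, probability = x$turn_prob)
  )
}

#' @rdname tidy.movement_kernel
#' @export
glance.movement_kernel <- function(x, ...) {
  tibble(source_track_id = x$source_track_id, n_steps = x$n_steps_emp,
         mean_step_m = x$mean_step, median_step_m = x$median_step,
         circ_mean_turn_rad = x$circ_mean_turn, eps_m = x$eps)
}

#' Plot the gut-retention probability curve
#' @param object A [retention_model()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.retention_model <- function(object, ...) {
  tidy(object) %>%
    ggplot(aes(.data$day, .data$probability)) +
    geom_col(fill = "tan4") +
    labs(x = "days since ingestion", y = expression(R[d]),
         title = "Daily seed-excretion probability") +
    theme_minimal()
}

#' Map a grid layer as filled hexagons
#'
#' @param grid A `hex_grid`.
#' @param layer Column name to map to fill.
#' @return A ggplot.
#' @export
plot_grid_layer <- function(grid, layer = "elevation") {
  verts <- hex_vertices(grid) %>%
    left_join(as_tibble(grid)[, c("cell_id", layer)], by = "cell_id")
  ggplot(verts, aes(.data$x, .data$y, group = .data$cell_id,
                    fill = .data[[layer]])) +
    geom_polygon(color = NA) +
    coord_equal() +
    labs(x = NULL, y = NULL, fill = layer) +
    theme_minimal()
}

#' Plot seed rain (or fate) on the hex grid
#' @param object A `seed_rain`.
#' @param grid The `hex_grid` it was accumulated on.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.seed_rain <- function(object, grid, ...) {
  verts <- hex_vertices(grid) %>%
    left_join(as_tibble(object)[, c("cell_id", "total_seeds")], by = "cell_id")
  ggplot(verts, aes(.data$x, .data$y, group = .data$cell_id,
                    fill = log10(.data$total_seeds + 1))) +
    geom_polygon(color = NA) +
    scale_fill_viridis_c() +
    coord_equal() +
    labs(x = NULL, y = NULL, fill = "log10(seeds + 1)",
         title = "Simulated seed rain") +
    theme_minimal()
}

#' Plot simulated trajectories
#' @param trajectories Output of [run_population()].
#' @param max_individuals Plot at most this many individuals.
#' @return A ggplot.
#' @export
plot_trajectories <- function(trajectories, max_individuals = 100) {
  ids <- unique(trajectories$individual_id)
  keep <- ids[seq_len(min(length(ids), max_individuals))]
  trajectories %>%
    filter(.data$individual_id %in% keep) %>%
    ggplot(aes(.data$x, .data$y, group = .data$individual_id)) +
    geom_path(alpha = 0.25, color = "darkgreen") +
    coord_equal() +
    labs(x = NULL, y = NULL, title = "Simulated migration trajectories") +
    theme_minimal()
}

#' Per-repeat elevation density of deposition events
#' @param events Event tibble with `elevation` and `repeat_id`.
#' @return A ggplot echoing the stochastic envelope across repeats.
#' @export
plot_deposition_elevation <- function(events) {
  if (!"repeat_id" %in% names(events)) events$repeat_id <- 1L
  ggplot(events, aes(.data$elevation, group = .data$repeat_id)) +
    ggplot2::geom_density(bw = "nrd0", color = "grey40", alpha = 0.4) +
    labs(x = "elevation (m)", y = "density",
         title = "Elevation distribution of deposition events") +
    theme_minimal()
}
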