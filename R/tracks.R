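#' Read animal tracks from a Movebank-style CSV
#'
#' Expects columns `individual_id`, `timestamp` (ISO-8601), `lon`, `lat`;
#' extra columns (e.g. a pre-segmented `phase` label) are carried through.
#'
#' @param path CSV file path.
#' @param tz Timezone for timestamp parsing (default UTC).
#' @return Tibble sorted by individual and time.
#' @export
read_tracks <- function(path, tz = "UTC") {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("individual_id", "timestamp", "lon", "lat")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(paste("track file lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  df$timestamp <- as.POSIXct(df$timestamp, tz = tz)
  df %>% arrange(.data$individual_id, .data$timestamp)
}

#' Project track coordinates into local metres
#'
#' Adds `x`/`y` columns (metres) via the local tangent-plane projection. If
#' the track already carries `x`/`y` it is returned unchanged.
#'
#' @param tracks Track tibble with `lon`/`lat`.
#' @param origin `c(lon0, lat0)` projection anchor; defaults to the first fix.
#' @return Track tibble with `x`, `y` columns.
#' @export
project_tracks <- function(tracks, origin = NULL) {
  if (all(c("x", "y") %in% names(tracks))) return(tracks)
  if (is.null(origin)) origin <- c(tracks$lon[1], tracks$lat[1])
  xy <- lonlat_to_xy(tracks$lon, tracks$lat, origin)
  tracks$x <- xy$x
  tracks$y <- xy$y
  tracks
}

check_track <- function(track, min_fixes = 2) {
  if (nrow(track) < min_fixes) {
    abort(sprintf("track needs at least %d fixes, got %d", min_fixes, nrow(track)))
  }
  by_id <- split(track$timestamp, track$individual_id)
  if (any(vapply(by_id, function(t) any(diff(as.numeric(t)) <= 0), logical(1)))) {
    abort("timestamps must be strictly increasing within each individual")
  }
  invisible(track)
}

#' Net squared displacement
#'
#' Squared planar distance (m^2) of every fix from the individual's first
#' fix. Sustained NSD increase is the classic signature of migration onset
#' in telemetry series.
#'
#' @param track Track tibble (one or more individuals); projected with
#'   [project_tracks()] if `x`/`y` are absent.
#' @return Tibble with `individual_id`, `timestamp`, `nsd_m2` (first value 0
#'   per individual).
#' @export
compute_nsd <- function(track) {
  check_track(track, 2)
  track <- project_tracks(track)
  track %>%
    group_by(.data$individual_id) %>%
    mutate(nsd_m2 = (.data$x - first(.data$x))^2 + (.data$y - first(.data$y))^2) %>%
    ungroup() %>%
    select("individual_id", "timestamp", "nsd_m2")
}

#' Thin a track to one fix per calendar day
#'
#' Retains the first fix of each calendar day (UTC date of the timestamp),
#' the temporal resolution assumed by the trajectory and dispersal models
#' (one relocation and one stop per day). Idempotent.
#'
#' @param track Track tibble.
#' @return Thinned track tibble, all columns preserved.
#' @export
thin_daily <- function(track) {
  check_track(track, 1)
  track %>%
    group_by(.data$individual_id, .day = as.Date(.data$timestamp, tz = "UTC")) %>%
    slice(1) %>%
    ungroup() %>%
    select(-".day") %>%
    arrange(.data$individual_id, .data$timestamp)
}

#' Flag candidate migration windows from NSD series
#'
#' A reproducible alternative to interactive segmentation: flags runs of at
#' least `min_days` consecutive daily NSD increases whose cumulative rise
#' exceeds `threshold_m2`.
#'
#' @param nsd Output of [compute_nsd()] on a daily-thinned track.
#' @param threshold_m2 Minimum cumulative NSD rise over the run (default
#'   1e6, i.e. a net displacement of 1 km).
#' @param min_days Minimum run length in fixes.
#' @return Input tibble with a logical `migrating` column.
#' @export
flag_migration_windows <- function(nsd, threshold_m2 = 1e6, min_days = 3) {
  nsd %>%
    group_by(.data$individual_id) %>%
    mutate(migrating = {
      d <- c(0, diff(.data$nsd_m2))
      up <- d > 0
      run <- rle(up)
      flag <- logical(length(up))
      ends <- cumsum(run$lengths)
      starts <- ends - run$lengths + 1
      for (k in seq_along(run$lengths)) {
        if (run$values[k] && run$lengths[k] >= min_days &&
            sum(d[starts[k]:ends[k]]) >= threshold_m2) {
          flag[starts[k]:ends[k]] <- TRUE
        }
      }
      flag
    }) %>%
    ungroup()
}
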