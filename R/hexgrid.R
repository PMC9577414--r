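#' Build an equal-area hexagonal grid over a rectangular domain
#'
#' Constructs a flat-topped hexagonal tessellation whose cells all share the
#' same target area, the discretization used to convert seasonal ranges into
#' site-level energy distributions and to accumulate seed deposition.
#'
#' @param extent_km Width and height of the square domain, in km.
#' @param hex_area_km2 Target cell area in km^2 (default 1.18).
#' @param origin_lon,origin_lat Geographic anchor of the local projection;
#'   the domain's lower-left corner maps to this lon/lat.
#' @return A tibble of class `hex_grid` with one row per cell: `cell_id`,
#'   axial coordinates `q`/`r`, centroid `x`/`y` in metres, and `area_km2`.
#'   Environmental layers (elevation, NDVI, ...) are added by downstream
#'   generators or loaders as plain columns.
#' @export
hex_grid <- function(extent_km, hex_area_km2 = 1.18,
                     origin_lon = -90.0, origin_lat = -0.6) {
  stopifnot(extent_km > 0, hex_area_km2 > 0)
  ext <- extent_km * 1000
  s <- sqrt(2 * hex_area_km2 * 1e6 / (3 * sqrt(3)))  # side length, m

  # flat-top axial layout: x = 1.5 s q ; y = sqrt(3) s (r + q/2)
  qmax <- ceiling(ext / (1.5 * s)) + 1
  rmax <- ceiling(ext / (sqrt(3) * s)) + qmax
  qr <- expand.grid(q = 0:qmax, r = (-qmax - 1):rmax)
  x <- 1.5 * s * qr$q
  y <- sqrt(3) * s * (qr$r + qr$q / 2)
  keep <- x >= -s & x <= ext + s & y >= -s & y <= ext + s
  grid <- tibble(
    cell_id = seq_len(sum(keep)),
    q = qr$q[keep], r = qr$r[keep],
    x = x[keep], y = y[keep],
    area_km2 = hex_area_km2
  )
  attr(grid, "hex_side_m") <- s
  attr(grid, "extent_m") <- ext
  attr(grid, "origin_lonlat") <- c(origin_lon, origin_lat)
  class(grid) <- c("hex_grid", class(grid))
  grid
}

# axial key used for O(1) cell lookup
hex_key <- function(q, r) q * 1e6 + r

#' Locate grid cells containing points
#'
#' Maps projected coordinates (metres) to the hexagonal cell containing them,
#' via axial-coordinate cube rounding. Points outside the grid return `NA`.
#'
#' @param grid A `hex_grid`.
#' @param x,y Numeric vectors of projected coordinates in metres.
#' @return Integer vector of `cell_id`s (NA where no cell exists).
#' @export
cells_at <- function(grid, x, y) {
  s <- attr(grid, "hex_side_m")
  qf <- (2 / 3) * x / s
  rf <- (-x / 3 + sqrt(3) / 3 * y) / s
  # cube rounding
  xf <- qf; zf <- rf; yf <- -xf - zf
  rx <- round(xf); ry <- round(yf); rz <- round(zf)
  dx <- abs(rx - xf); dy <- abs(ry - yf); dz <- abs(rz - zf)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  idx <- match(hex_key(rx, rz), hex_key(grid$q, grid$r))
  grid$cell_id[idx]
}

#' Hexagon outlines for plotting
#'
#' @param grid A `hex_grid`.
#' @return Tibble with `cell_id`, `vertex`, `x`, `y` (six vertices per cell).
#' @export
hex_vertices <- function(grid) {
  s <- attr(grid, "hex_side_m")
  ang <- (0:5) * pi / 3
  tidyr::crossing(cell = seq_len(nrow(grid)), vertex = 1:6) %>%
    mutate(
      cell_id = grid$cell_id[.data$cell],
      x = grid$x[.data$cell] + s * cos(ang[.data$vertex]),
      y = grid$y[.data$cell] + s * sin(ang[.data$vertex])
    ) %>%
    select("cell_id", "vertex", "x", "y")
}

#' Local tangent-plane projection between lon/lat and metres
#'
#' An equirectangular projection anchored at the grid origin; adequate for
#' island-scale domains (tens of km) where scale distortion is negligible.
#'
#' @param lon,lat Geographic coordinates (degrees).
#' @param origin Length-2 numeric, `c(lon0, lat0)`.
#' @return `lonlat_to_xy`: tibble with `x`, `y` in metres;
#'   `xy_to_lonlat`: tibble with `lon`, `lat`.
#' @export
lonlat_to_xy <- function(lon, lat, origin) {
  R <- 6371008.8
  tibble(
    x = (lon - origin[1]) * pi / 180 * R * cos(origin[2] * pi / 180),
    y = (lat - origin[2]) * pi / 180 * R
  )
}

#' @rdname lonlat_to_xy
#' @param x,y Projected coordinates in metres.
#' @export
xy_to_lonlat <- function(x, y, origin) {
  R <- 6371008.8
  tibble(
    lon = origin[1] + x / (R * cos(origin[2] * pi / 180)) * 180 / pi,
    lat = origin[2] + y / R * 180 / pi
  )
}
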