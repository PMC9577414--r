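#' Estimate a utilization-distribution isopleth polygon
#'
#' Kernel density estimation (bivariate normal kernel, normal-reference
#' bandwidth) of an individual's space use, returning the polygon enclosing
#' the requested fraction of the estimated density mass (the UD isopleth,
#' default 95%). With fewer than 30 fixes a kernel estimate is unreliable:
#' the function warns and falls back to the convex hull of the fixes.
#'
#' @param track Track tibble for a single individual (projected metres; if
#'   `x`/`y` absent, [project_tracks()] is applied).
#' @param isopleth Density mass fraction to enclose, in (0, 1\]; default 0.95.
#' @param grid_n KDE evaluation grid resolution per axis.
#' @return A `ud_polygon`: tibble with `ring`, `x`, `y` vertex rows;
#'   attributes `isopleth`, `level`, `area_km2`.
#' @export
estimate_ud <- function(track, isopleth = 0.95, grid_n = 128) {
  stopifnot(isopleth > 0, isopleth <= 1)
  track <- project_tracks(track)
  x <- track$x; y <- track$y
  if (sd(x) == 0 && sd(y) == 0) abort("all fixes identical: degenerate kernel")

  if (nrow(track) < 30) {
    warn(sprintf("only %d fixes (< 30): falling back to convex hull", nrow(track)))
    h <- chull(x, y)
    return(new_ud_polygon(tibble(ring = 1L, x = x[h], y = y[h]),
                          isopleth = isopleth, level = NA_real_))
  }

  bw <- function(v) {
    b <- MASS::bandwidth.nrd(v)
    if (!is.finite(b) || b <= 0) b <- max(diff(range(v)) / 10, 1)
    b
  }
  hx <- bw(x); hy <- bw(y)
  lims <- c(range(x) + c(-1, 1) * hx, range(y) + c(-1, 1) * hy)
  kd <- MASS::kde2d(x, y, h = c(hx, hy), n = grid_n, lims = lims)

  z <- kd$z / sum(kd$z)
  zs <- sort(as.vector(z), decreasing = TRUE)
  idx <- which(cumsum(zs) >= isopleth)[1]
  level <- if (is.na(idx)) min(zs) / 2 else zs[idx]
  level_abs <- level * sum(kd$z)  # back to density scale of kd$z

  if (isopleth >= 0.999 || level_abs <= min(kd$z)) {
    # the region is (essentially) the whole evaluation window
    poly <- tibble(ring = 1L,
                   x = lims[c(1, 2, 2, 1)], y = lims[c(3, 3, 4, 4)])
    return(new_ud_polygon(poly, isopleth = isopleth, level = level_abs))
  }

  cl <- contourLines(kd$x, kd$y, kd$z, levels = level_abs * 0.999999)
  if (length(cl) == 0) {
    # level below the entire surface: the isopleth region is the whole window
    poly <- tibble(ring = 1L,
                   x = lims[c(1, 2, 2, 1)], y = lims[c(3, 3, 4, 4)])
  } else {
    poly <- bind_rows(lapply(seq_along(cl), function(i) {
      tibble(ring = i, x = cl[[i]]$x, y = cl[[i]]$y)
    }))
  }
  new_ud_polygon(poly, isopleth = isopleth, level = level_abs)
}

new_ud_polygon <- function(poly, isopleth, level) {
  area <- sum(vapply(split(poly, poly$ring),
                     function(rg) ring_area(rg$x, rg$y), numeric(1)))
  attr(poly, "isopleth") <- isopleth
  attr(poly, "level") <- level
  attr(poly, "area_km2") <- area / 1e6
  class(poly) <- c("ud_polygon", class(poly))
  poly
}

#' Polygon area in km^2
#' @param poly A `ud_polygon` or tibble with `ring`, `x`, `y`.
#' @return Numeric scalar.
#' @export
polygon_area_km2 <- function(poly) {
  if (!"ring" %in% names(poly)) poly$ring <- 1L
  sum(vapply(split(poly, poly$ring),
             function(rg) ring_area(rg$x, rg$y), numeric(1))) / 1e6
}

# Point-in-polygon over possibly multi-ring boundaries (mgcv::in.out wants
# NA-separated rings).
points_in_polygon <- function(px, py, poly) {
  if (!"ring" %in% names(poly)) poly$ring <- 1L
  rings <- split(poly, poly$ring)
  bnd <- do.call(rbind, lapply(rings, function(rg) {
    rbind(cbind(rg$x, rg$y), c(rg$x[1], rg$y[1]), c(NA, NA))
  }))
  mgcv::in.out(bnd, cbind(px, py))
}

#' Population-level seasonal range on the hex grid
#'
#' Takes the convex hull around a set of individual UD polygons and converts
#' it to presence/absence on the grid: member cells are those whose centroid
#' falls inside the hull.
#'
#' @param uds A `ud_polygon` or list of them.
#' @param grid A `hex_grid`.
#' @param season Label, e.g. `"highland"` or `"lowland"`.
#' @return Object of class `seasonal_range`: list with `season`,
#'   `member_cells` (integer cell ids) and `hull` (tibble of vertices).
#' @export
seasonal_range <- function(uds, grid, season = "unlabeled") {
  if (inherits(uds, "ud_polygon")) uds <- list(uds)
  stopifnot(length(uds) >= 1)
  verts <- bind_rows(lapply(uds, function(p) tibble(x = p$x, y = p$y)))
  h <- chull(verts$x, verts$y)
  hull <- tibble(ring = 1L, x = verts$x[h], y = verts$y[h])
  inside <- points_in_polygon(grid$x, grid$y, hull)
  if (!any(inside)) abort("seasonal range hull contains no cell centroid")
  structure(
    list(season = season,
         member_cells = grid$cell_id[inside],
         hull = hull),
    class = "seasonal_range"
  )
}

#' @export
print.seasonal_range <- function(x, ...) {
  cat(sprintf("Seasonal range '%s': %d cells, hull area %.1f km^2\n",
              x$season, length(x$member_cells), polygon_area_km2(x$hull)))
  invisible(x)
}
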