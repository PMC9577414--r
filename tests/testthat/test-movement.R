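test_that("net squared displacement has the closed-form values", {
  tr <- line_track(3, step_m = 100)
  nsd <- compute_nsd(tr)
  expect_equal(nsd$nsd_m2, c(0, 1e4, 4e4))

  # out-and-back: final NSD returns to zero
  back <- tr
  back$x <- c(0, 100, 0)
  expect_equal(compute_nsd(back)$nsd_m2[3], 0)

  expect_error(compute_nsd(line_track(1)), "at least 2")
})

test_that("NSD agrees with a haversine oracle and rises along a migration", {
  b <- small_island()
  tr <- b$tracks[b$tracks$individual_id == b$tracks$individual_id[1], ]
  nsd <- compute_nsd(dplyr::select(tr, -x, -y))  # force lon/lat route
  oracle <- oracle_haversine_nsd(tr$lon, tr$lat)
  expect_lt(max(abs(nsd$nsd_m2 - oracle)) / max(oracle), 0.01)
  # monotone in expectation along the downslope leg: late >> early
  mig <- which(tr$phase == "migration")
  expect_gt(mean(nsd$nsd_m2[tail(mig, 5)]), mean(nsd$nsd_m2[head(mig, 5)]))
})

test_that("daily thinning keeps the first fix of each day and is idempotent", {
  hourly <- tibble::tibble(
    individual_id = "h",
    timestamp = as.POSIXct("2020-03-01 00:00:00", tz = "UTC") + (0:71) * 3600,
    lon = runif(72), lat = runif(72))
  th <- thin_daily(hourly)
  expect_equal(nrow(th), 3)
  expect_equal(as.Date(th$timestamp), as.Date(c("2020-03-01", "2020-03-02", "2020-03-03")))
  expect_equal(format(th$timestamp, "%H"), rep("00", 3))
  expect_identical(thin_daily(th), th)

  daily <- line_track(5)
  expect_identical(thin_daily(daily), daily)
})

test_that("UD isopleth polygons bound the density mass correctly", {
  set.seed(42)
  sigma <- 500
  pts <- tibble::tibble(
    individual_id = "g",
    timestamp = as.POSIXct("2020-01-01", tz = "UTC") + (1:2000) * 86400,
    x = rnorm(2000, 0, sigma), y = rnorm(2000, 0, sigma),
    lon = 0, lat = 0)
  ud95 <- estimate_ud(pts, isopleth = 0.95)
  # analytic area of the Gaussian 95% probability region
  analytic <- pi * sigma^2 * qchisq(0.95, df = 2) / 1e6
  expect_lt(abs(attr(ud95, "area_km2") - analytic) / analytic, 0.15)

  # nesting: the 50% region sits inside the 95% region and is smaller
  ud50 <- estimate_ud(pts, isopleth = 0.50)
  expect_lt(attr(ud50, "area_km2"), attr(ud95, "area_km2"))
  expect_true(all(seedrain:::points_in_polygon(ud50$x, ud50$y, ud95)))

  # isopleth 1 contains every fix
  ud100 <- estimate_ud(pts, isopleth = 1)
  expect_true(all(seedrain:::points_in_polygon(pts$x, pts$y, ud100)))
})

test_that("degenerate and undersized tracks are handled", {
  same <- line_track(40, step_m = 0)
  expect_error(estimate_ud(same), "identical")
  few <- bcrw_track(15, seed = 2)
  expect_warning(ud <- estimate_ud(few), "convex hull")
  expect_true(all(seedrain:::points_in_polygon(few$x, few$y, ud) |
                    paste(few$x, few$y) %in% paste(ud$x, ud$y)))
})

test_that("seasonal ranges convert UD hulls to cell membership", {
  g <- flat_grid(8)
  # polygon drawn around exactly three adjacent cell centroids
  three <- g[order((g$x - 4000)^2 + (g$y - 4000)^2), ][1:3, ]
  pad <- 80
  poly <- tibble::tibble(
    ring = 1L,
    x = c(min(three$x) - pad, max(three$x) + pad, max(three$x) + pad, min(three$x) - pad),
    y = c(min(three$y) - pad, min(three$y) - pad, max(three$y) + pad, max(three$y) + pad))
  class(poly) <- c("ud_polygon", class(poly))
  rng <- seasonal_range(list(poly), g, season = "test")
  expect_setequal(rng$member_cells, three$cell_id)

  # hull far outside the grid: no centroids
  off <- poly; off$x <- off$x + 1e6
  expect_error(seasonal_range(list(off), g), "no cell centroid")
})

test_that("estimated seasonal ranges recover the generator's bands", {
  b <- default_island()
  rng <- seasonal_ranges_from_tracks(b$tracks, b$grid)
  jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  expect_gte(jaccard(rng$highland$member_cells, b$highland_cells), 0.8)
  expect_gte(jaccard(rng$lowland$member_cells, b$lowland_cells), 0.8)
  expect_false(setequal(rng$highland$member_cells, rng$lowland$member_cells))

  # highland range stays within the highland elevation band, allowing one
  # ring of boundary cells (the hull pads each UD by its kernel bandwidth)
  g <- b$grid
  hb <- b$config$highland_band_m
  elev <- g$elevation[match(rng$highland$member_cells, g$cell_id)]
  ring_m <- 2 * sqrt(1.18e6 / pi)  # one cell diameter
  slope <- b$config$elevation_peak_m / (attr(g, "extent_m") / 2)
  expect_true(all(elev >= hb[1] - 3 * ring_m * slope))
})

test_that("migration windows are flagged from sustained NSD rise", {
  b <- small_island()
  tr <- b$tracks[b$tracks$individual_id == b$tracks$individual_id[1], ]
  flagged <- flag_migration_windows(compute_nsd(tr), threshold_m2 = 4e6)
  expect_true(any(flagged$migrating))
  # flags concentrate on the migration leg
  expect_gt(mean(flagged$migrating[tr$phase == "migration"]),
            mean(flagged$migrating[tr$phase == "highland_residency"]))
})
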