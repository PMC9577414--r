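test_that("source-plant coverage matches the configured highland fraction", {
  # zero case
  b0 <- generate_island(island_config(extent_km = 16, n_tracks = 1,
                                      guava_highland_fraction = 0,
                                      rng_seed = 5L),
                        make_dung_piles = FALSE)
  expect_false(any(b0$grid$guava))

  # default fraction on a domain with > 500 highland cells
  b <- generate_island(island_config(extent_km = 110, n_tracks = 1,
                                     rng_seed = 6L),
                       make_dung_piles = FALSE)
  expect_gte(length(b$highland_cells), 500)
  frac <- mean(b$grid$guava[match(b$highland_cells, b$grid$cell_id)])
  expect_gte(frac, 0.19)
  expect_lte(frac, 0.23)
  # source plants only in the highland band
  expect_true(all(b$grid$cell_id[b$grid$guava] %in% b$highland_cells))
})

test_that("fixed seed gives byte-identical bundles", {
  cfg <- island_config(extent_km = 16, n_tracks = 4, rng_seed = 77L)
  b1 <- generate_island(cfg, make_dung_piles = TRUE)
  b2 <- generate_island(cfg, make_dung_piles = TRUE)
  expect_identical(b1, b2)
})

test_that("island structure: radial elevation decay, NDVI gradient, equal-area cells", {
  b <- small_island()
  g <- b$grid
  ext <- attr(g, "extent_m")
  r <- sqrt((g$x - ext / 2)^2 + (g$y - ext / 2)^2)
  # binned mean elevation decreases outward from the island centre
  bins <- cut(r, seq(0, max(r) + 1, length.out = 8))
  mean_by_bin <- tapply(g$elevation, bins, mean)
  mean_by_bin <- mean_by_bin[!is.na(mean_by_bin)]
  # decreasing in expectation: allow the 5 m noise sd at the flat coast
  expect_true(all(diff(mean_by_bin) < 5))
  expect_lt(cor(r, g$elevation), -0.9)
  # NDVI decreases with elevation (lowlands greener)
  expect_lt(cor(g$elevation, g$ndvi), -0.9)
  expect_true(all(abs(g$area_km2 - 1.18) / 1.18 < 0.01))
  expect_false(any(duplicated(g$cell_id)))
})

test_that("synthetic tracks run downslope with serially correlated headings", {
  b <- small_island()
  g <- b$grid
  for (id in unique(b$tracks$individual_id)) {
    tr <- b$tracks[b$tracks$individual_id == id, ]
    expect_gte(nrow(tr), 10)
    start_cell <- cells_at(g, tr$x[1], tr$y[1])
    end_cell <- cells_at(g, tr$x[nrow(tr)], tr$y[nrow(tr)])
    expect_true(start_cell %in% b$highland_cells)
    expect_true(end_cell %in% b$lowland_cells)
    # net downslope displacement
    elev <- g$elevation[match(c(start_cell, end_cell), g$cell_id)]
    expect_lt(elev[2], elev[1])
  }
  # heading autocorrelation on the migration leg: consecutive headings agree
  mig <- b$tracks[b$tracks$phase == "migration", ]
  tr1 <- mig[mig$individual_id == mig$individual_id[1], ]
  hd <- atan2(diff(tr1$y), diff(tr1$x))
  expect_gt(mean(cos(diff(hd))), 0.5)
})

test_that("kernel fitting recovers the generator's step-length scale", {
  # long track drawn from the generator's parametric family
  tr <- bcrw_track(2000, shape = 5, scale = 120, turn_sd = 0.5, seed = 9)
  k <- fit_movement_kernel(tr)
  expect_lt(abs(k$mean_step - 5 * 120) / (5 * 120), 0.03)
})

test_that("degenerate seasonal bands raise explicit errors", {
  expect_error(
    generate_island(island_config(extent_km = 16, highland_band_m = c(5000, 6000),
                                  rng_seed = 1L), make_dung_piles = FALSE),
    "highland band")
  expect_error(island_config(highland_band_m = c(100, 600),
                             lowland_band_m = c(0, 150)),
               "overlap")
})

test_that("synthetic dung piles carry the validation-record structure", {
  b <- default_island()
  dp <- b$dung_piles
  expect_true(all(c("x", "y", "elevation", "contains_guava", "landcover",
                    "zone", "source") %in% names(dp)))
  expect_gt(sum(dp$contains_guava), 50)
  expect_gt(sum(!dp$contains_guava), 50)
  expect_true(all(is.finite(dp$elevation)))
  expect_true(all(dp$landcover %in% unique(b$grid$landcover)))
})
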