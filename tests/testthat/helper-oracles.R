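# Independent oracles used by the tests. Each is deliberately a different
# route to the answer than the package implementation.

# Two-piece right-skewed normal density, written directly from the
# piecewise definition (scaled half-Gaussians, then standardized to the
# requested mean/sd) rather than via the package's vectorized form.
oracle_skewnorm_density <- function(x, mean, sd, xi) {
  m1 <- sqrt(2 / pi)
  mu_z <- m1 * (xi - 1 / xi)
  sd_z <- sqrt((1 - m1^2) * (xi^2 + 1 / xi^2) + 2 * m1^2 - 1)
  f_std <- function(z) {
    if (z < 0) 2 / (xi + 1 / xi) * stats::dnorm(xi * z)
    else       2 / (xi + 1 / xi) * stats::dnorm(z / xi)
  }
  vapply(x, function(xx) {
    z <- (xx - mean) / sd * sd_z + mu_z
    f_std(z) * sd_z / sd
  }, numeric(1))
}

# Exhaustive two-sample KS statistic: evaluate |F_a - F_b| at every pooled
# observation by explicit double loops over the samples.
oracle_ks_D <- function(a, b) {
  pts <- c(a, b)
  D <- 0
  for (t in pts) {
    Fa <- sum(a <= t) / length(a)
    Fb <- sum(b <= t) / length(b)
    D <- max(D, abs(Fa - Fb))
  }
  D
}

# Haversine NSD oracle (great-circle distances on the sphere).
oracle_haversine_nsd <- function(lon, lat) {
  R <- 6371008.8
  toRad <- pi / 180
  d <- vapply(seq_along(lon), function(i) {
    dlat <- (lat[i] - lat[1]) * toRad
    dlon <- (lon[i] - lon[1]) * toRad
    a <- sin(dlat / 2)^2 +
      cos(lat[1] * toRad) * cos(lat[i] * toRad) * sin(dlon / 2)^2
    2 * R * asin(pmin(1, sqrt(a)))
  }, numeric(1))
  d^2
}

# Exact LP solutions for small transportation instances via scipy's HiGHS
# solver (one python call for a whole batch). Returns the optimal costs.
oracle_lp_costs <- function(instances) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(instances, infile, auto_unbox = FALSE, digits = NA)
  py <- Sys.which("python")
  expect_true(nzchar(py))
  status <- system2(py, c(test_path("oracle_lp.py"), infile, outfile))
  expect_equal(status, 0L)
  unlist(jsonlite::read_json(outfile, simplifyVector = TRUE))
}
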