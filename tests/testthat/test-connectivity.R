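test_that("energy weights are proportional to NDVI and rescale to the population", {
  g <- flat_grid(8)
  rng <- structure(list(season = "highland",
                        member_cells = g$cell_id[1:4], hull = NULL),
                   class = "seasonal_range")
  g$ndvi <- 0.5
  H <- energy_from_ndvi(g, rng, 8)
  expect_equal(H$weight, rep(2, 4))

  g$ndvi[match(rng$member_cells, g$cell_id)] <- c(0.2, 0.4, 0, 0)
  rng2 <- rng; rng2$member_cells <- rng$member_cells[1:2]
  H2 <- energy_from_ndvi(g, rng2, 3)
  expect_equal(H2$weight, c(1, 2))

  for (pop in c(7, 100, 1000)) {
    Hp <- energy_from_ndvi(g, rng, pop)
    expect_equal(sum(Hp$weight), pop)
  }
  g$ndvi <- 0
  expect_error(energy_from_ndvi(g, rng, 10), "all-zero NDVI")
})

test_that("relocation costs are centroid distances in km", {
  g <- flat_grid(10)
  H <- energy_dist(g$cell_id[1:5], rep(1, 5))
  L <- energy_dist(g$cell_id[3:8], rep(1, 6))
  cc <- transport_cost(g, H, L)
  expect_equal(cc[3, 1], 0)  # same cell
  d12 <- sqrt((g$x[1] - g$x[4])^2 + (g$y[1] - g$y[4])^2) / 1000
  expect_equal(cc[1, 2], d12)
  # symmetry in arguments
  expect_equal(t(transport_cost(g, L, H)), cc)
  # triangle inequality over random cell triples
  withr::with_seed(4, {
    full <- energy_dist(g$cell_id, rep(1, nrow(g)))
    cm <- transport_cost(g, full, full)
    for (rep in 1:200) {
      ijk <- sample(nrow(g), 3)
      expect_lte(cm[ijk[1], ijk[3]],
                 cm[ijk[1], ijk[2]] + cm[ijk[2], ijk[3]] + 1e-9)
    }
  })
})

test_that("transport solution satisfies the four flow constraints", {
  withr::with_seed(10, {
    for (trial in 1:25) {
      m <- sample(2:5, 1); n <- sample(2:5, 1)
      H <- energy_dist(1:m, runif(m, 0.5, 4))
      L <- energy_dist(m + 1:n, runif(n, 0.5, 4))
      costs <- matrix(runif(m * n, 0.1, 10), m, n)
      fl <- solve_transport(H, L, costs)
      f <- attr(fl, "f")
      expect_true(all(f >= 0))                                  # (1)
      expect_true(all(rowSums(f) <= H$weight + 1e-6))           # (2)
      expect_true(all(colSums(f) <= L$weight + 1e-6))           # (3)
      expect_equal(sum(f), min(sum(H$weight), sum(L$weight)),
                   tolerance = 1e-6)                            # (4)
    }
  })
})

test_that("small instances reproduce hand-solved optima", {
  H <- energy_dist("h1", 5)
  L <- energy_dist("l1", 5)
  fl <- solve_transport(H, L, matrix(3))
  expect_equal(fl$flow, 5)
  expect_equal(attr(fl, "total_cost"), 15)

  # unbalanced: supply 10, demand 7 -> total flow 7
  H2 <- energy_dist(c("a", "b"), c(6, 4))
  L2 <- energy_dist(c("x", "y"), c(3, 4))
  fl2 <- solve_transport(H2, L2, matrix(c(1, 2, 2, 1), 2, 2))
  expect_equal(attr(fl2, "total_flow"), 7)
  expect_equal(attr(fl2, "total_cost"), 3 * 1 + 4 * 1)
})

test_that("no profitable two-route swap exists in the optimal flow (swap optimality)", {
  b <- small_island()
  g <- b$grid
  H <- energy_dist(b$highland_cells,
                   g$ndvi[match(b$highland_cells, g$cell_id)])
  L <- energy_dist(b$lowland_cells,
                   g$ndvi[match(b$lowland_cells, g$cell_id)])
  H$weight <- H$weight / sum(H$weight) * 50
  L$weight <- L$weight / sum(L$weight) * 50
  costs <- transport_cost(g, H, L)
  fl <- solve_transport(H, L, costs)
  f <- attr(fl, "f")
  used <- which(f > 1e-9, arr.ind = TRUE)
  for (p in seq_len(nrow(used))) {
    for (q in seq_len(nrow(used))) {
      i1 <- used[p, 1]; j1 <- used[p, 2]
      i2 <- used[q, 1]; j2 <- used[q, 2]
      # rerouting epsilon from (i1,j1),(i2,j2) to (i1,j2),(i2,j1) must not
      # reduce total cost
      delta <- costs[i1, j2] + costs[i2, j1] - costs[i1, j1] - costs[i2, j2]
      expect_gte(delta, -1e-8)
    }
  }
})

test_that("a single lowland site holding all energy receives every individual", {
  H <- energy_dist(1:3, c(2, 3, 5))
  L <- energy_dist(4:6, c(10, 0, 0))
  costs <- matrix(runif(9, 1, 5), 3, 3)
  fl <- solve_transport(H, L, costs)
  asg <- assign_individuals(fl, 10)
  expect_true(all(asg$dest_cell == 4))
  expect_equal(nrow(asg), 10)
})

test_that("largest-remainder integerization conserves the population exactly", {
  fl <- tibble::tibble(origin_cell = c(1, 2), dest_cell = c(10, 11),
                       flow = c(2, 3))
  attr(fl, "total_flow") <- 5
  class(fl) <- c("flow_matrix", class(fl))
  asg <- assign_individuals(fl, 5)
  expect_equal(as.vector(table(asg$origin_cell)), c(2, 3))

  fl2 <- tibble::tibble(origin_cell = c(1, 1, 2), dest_cell = c(10, 11, 11),
                        flow = c(0.5, 0.5, 1.0))
  attr(fl2, "total_flow") <- 2
  class(fl2) <- c("flow_matrix", class(fl2))
  asg2 <- assign_individuals(fl2, 2)
  counts <- sapply(1:3, function(i) sum(asg2$origin_cell == fl2$origin_cell[i] &
                                          asg2$dest_cell == fl2$dest_cell[i]))
  expect_equal(sum(counts), 2)
  expect_true(all(abs(counts - fl2$flow) < 1))

  withr::with_seed(8, {
    for (trial in 1:100) {
      nr <- sample(3:12, 1)
      pop <- sample(5:500, 1)
      w <- runif(nr)
      fl3 <- tibble::tibble(origin_cell = seq_len(nr), dest_cell = seq_len(nr),
                            flow = w / sum(w) * pop)
      attr(fl3, "total_flow") <- pop
      class(fl3) <- c("flow_matrix", class(fl3))
      asg3 <- assign_individuals(fl3, pop)
      expect_equal(nrow(asg3), pop)
    }
  })
  expect_error(assign_individuals(fl, 0), "positive")
})
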