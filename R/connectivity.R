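#' Seasonal energy distribution from NDVI
#'
#' Converts the NDVI surface within a seasonal range into per-cell energy
#' weights, rescaled so the weights sum to the configured number of
#' migrating individuals (default framing: 1000). Energy per cell is
#' proportional to `max(NDVI, 0) * cell area`; on an equal-area grid this is
#' proportional to mean NDVI.
#'
#' @param grid A `hex_grid` with an `ndvi` column.
#' @param range A [seasonal_range()].
#' @param population_size Total weight after rescaling (number of migrants).
#' @return Object of class `seasonal_distribution`: tibble with `cell_id`,
#'   `weight`; attributes `season`, `population_size`.
#' @export
energy_from_ndvi <- function(grid, range, population_size = 1000) {
  stopifnot(inherits(range, "seasonal_range"), population_size >= 1)
  if (!"ndvi" %in% names(grid)) abort("grid has no `ndvi` layer")
  cells <- grid[match(range$member_cells, grid$cell_id), ]
  if (anyNA(cells$ndvi)) abort("NDVI undefined on some range cells")
  raw <- pmax(cells$ndvi, 0) * cells$area_km2
  if (sum(raw) <= 0) abort("all-zero NDVI within the seasonal range")
  out <- tibble(cell_id = cells$cell_id,
                weight = raw / sum(raw) * population_size)
  attr(out, "season") <- range$season
  attr(out, "population_size") <- population_size
  class(out) <- c("seasonal_distribution", class(out))
  out
}

#' Relocation cost matrix between seasonal sites
#'
#' The energetic cost of relocating between a highland and a lowland site is
#' proxied by the planar distance between their cell centroids, in km.
#'
#' @param grid A `hex_grid`.
#' @param H,L `seasonal_distribution`s (or anything with a `cell_id` column).
#' @return Numeric matrix, rows = H sites, cols = L sites, km.
#' @export
transport_cost <- function(grid, H, L) {
  hi <- match(H$cell_id, grid$cell_id)
  lj <- match(L$cell_id, grid$cell_id)
  dx <- outer(grid$x[hi], grid$x[lj], "-")
  dy <- outer(grid$y[hi], grid$y[lj], "-")
  sqrt(dx^2 + dy^2) / 1000
}

#' Solve the migratory-connectivity transportation problem
#'
#' Finds the flow matrix `f_ij >= 0` between highland supply sites and
#' lowland demand sites minimizing total relocation cost
#' `sum(c_ij * f_ij)` subject to row sums bounded by highland weights,
#' column sums bounded by lowland weights, and a grand total equal to
#' `min(sum supply, sum demand)` — the Monge-Kantorovich transportation
#' problem whose optimum is the Earth Mover's Distance flow. Solved exactly
#' by successive shortest augmenting paths with node potentials, so no
#' distance threshold or approximation is involved.
#'
#' @param H,L `seasonal_distribution`s (supply = highland, demand = lowland).
#' @param costs Cost matrix from [transport_cost()] (rows H, cols L).
#' @param tol Feasibility tolerance on the grand total.
#' @return Object of class `flow_matrix`: tibble of positive flows
#'   (`origin_cell`, `dest_cell`, `flow`) with attributes `total_flow`,
#'   `total_cost`, `supply`, `demand`, `f` (dense matrix), `costs`.
#' @export
solve_transport <- function(H, L, costs, tol = 1e-9) {
  if (nrow(H) == 0 || nrow(L) == 0) abort("empty seasonal distribution")
  a <- H$weight; b <- L$weight
  stopifnot(all(is.finite(costs)), all(a >= 0), all(b >= 0))
  m <- length(a); n <- length(b)
  stopifnot(nrow(costs) == m, ncol(costs) == n)
  target <- min(sum(a), sum(b))

  f <- matrix(0, m, n)
  pu <- numeric(m)  # supply potentials
  pv <- numeric(n)  # demand potentials
  rem_a <- a; rem_b <- b
  pushed <- 0

  while (pushed < target - tol) {
    # Dijkstra on reduced costs; nodes 1..m supplies, m+1..m+n demands.
    # `dd` is the tentative-distance vector with settled nodes masked out.
    d <- rep(Inf, m + n)
    parent <- integer(m + n)
    d[which(rem_a > tol)] <- 0
    dd <- d
    settled <- rep(FALSE, m + n)
    t_node <- 0L
    repeat {
      u <- which.min(dd)
      if (!is.finite(dd[u])) break
      settled[u] <- TRUE
      dd[u] <- Inf
      if (u > m && rem_b[u - m] > tol) { t_node <- u; break }
      if (u <= m) {
        nd <- d[u] + costs[u, ] + pu[u] - pv
        j_idx <- (m + 1):(m + n)
        upd <- !settled[j_idx] & nd < d[j_idx] - 1e-15
        if (any(upd)) {
          d[m + which(upd)] <- nd[upd]
          dd[m + which(upd)] <- nd[upd]
          parent[m + which(upd)] <- u
        }
      } else {
        j <- u - m
        has_flow <- f[, j] > tol
        if (any(has_flow)) {
          nd <- d[u] + pv[j] - costs[, j] - pu
          upd <- has_flow & !settled[1:m] & nd < d[1:m] - 1e-15
          if (any(upd)) {
            d[which(upd)] <- nd[upd]
            dd[which(upd)] <- nd[upd]
            parent[which(upd)] <- u
          }
        }
      }
    }
    if (t_node == 0L) abort("transportation problem infeasible (no augmenting path)")

    # potential update preserving nonnegative reduced costs
    dcap <- pmin(d, d[t_node])
    pu <- pu + dcap[1:m]
    pv <- pv + dcap[(m + 1):(m + n)]

    # reconstruct path target -> source; compute bottleneck
    path <- integer(0)
    v <- t_node
    while (v != 0L) { path <- c(v, path); v <- parent[v] }
    delta <- min(rem_b[t_node - m], target - pushed, rem_a[path[1]])
    if (length(path) > 2) {
      for (k in seq(2, length(path) - 1)) {
        if (path[k] > m && path[k + 1] <= m) {  # backward arc demand -> supply
          delta <- min(delta, f[path[k + 1], path[k] - m])
        }
      }
    }
    # apply augmentation along the path
    for (k in seq_len(length(path) - 1)) {
      u <- path[k]; v <- path[k + 1]
      if (u <= m && v > m) f[u, v - m] <- f[u, v - m] + delta
      else f[v, u - m] <- f[v, u - m] - delta
    }
    rem_a[path[1]] <- rem_a[path[1]] - delta
    rem_b[t_node - m] <- rem_b[t_node - m] - delta
    pushed <- pushed + delta
  }

  pos <- which(f > tol, arr.ind = TRUE)
  flows <- tibble(
    origin_cell = H$cell_id[pos[, 1]],
    dest_cell = L$cell_id[pos[, 2]],
    flow = f[pos]
  ) %>% arrange(.data$origin_cell, .data$dest_cell)
  attr(flows, "total_flow") <- sum(f)
  attr(flows, "total_cost") <- sum(costs * f)
  attr(flows, "supply") <- a
  attr(flows, "demand") <- b
  attr(flows, "f") <- f
  attr(flows, "costs") <- costs
  class(flows) <- c("flow_matrix", class(flows))
  flows
}

#' Integerize optimal flows into individual origin-destination assignments
#'
#' Converts the fractional optimal flow into whole migrating individuals by
#' largest-remainder rounding (deterministic; every rounded count is within
#' 1 of its flow and the counts sum exactly to `population_size`). A
#' stochastic multinomial alternative is available via `method`.
#'
#' @param flow A `flow_matrix`.
#' @param population_size Number of individuals; must match the grand total
#'   flow (within 0.5).
#' @param method `"largest_remainder"` (default) or `"multinomial"`.
#' @return Tibble with `individual_id`, `origin_cell`, `dest_cell`.
#' @export
assign_individuals <- function(flow, population_size,
                               method = c("largest_remainder", "multinomial")) {
  method <- match.arg(method)
  if (population_size <= 0) abort("`population_size` must be positive")
  total <- attr(flow, "total_flow")
  if (abs(total - population_size) > 0.5) {
    abort(sprintf("grand total flow (%.3f) does not match population size (%d)",
                  total, population_size))
  }
  fl <- flow$flow
  if (method == "largest_remainder") {
    base <- floor(fl)
    rem <- fl - base
    need <- as.integer(round(population_size - sum(base)))
    counts <- base
    if (need > 0) {
      ord <- order(rem, decreasing = TRUE)
      counts[ord[seq_len(need)]] <- counts[ord[seq_len(need)]] + 1
    }
  } else {
    counts <- as.vector(stats::rmultinom(1, population_size, fl / sum(fl)))
  }
  idx <- rep(seq_along(fl), counts)
  tibble(
    individual_id = sprintf("sim_%04d", seq_len(sum(counts))),
    origin_cell = flow$origin_cell[idx],
    dest_cell = flow$dest_cell[idx]
  )
}

#' @export
print.flow_matrix <- function(x, ...) {
  cat(sprintf("Optimal transport flow: %d routes, total flow %.3f, total cost %.2f\n",
              nrow(x), attr(x, "total_flow"), attr(x, "total_cost")))
  NextMethod()
}
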