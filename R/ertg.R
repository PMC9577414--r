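#' Number of daily steps for a simulated migration
#'
#' The trajectory generator needs a fixed step count. It is chosen so that
#' the origin-destination distance equals the expected net displacement of
#' an unconstrained walk from this kernel after that many days (read off the
#' kernel's pre-simulated k-step displacement table). This matches simulated
#' migration durations to the template's empirical geometry: a tortuous
#' template gets more days for the same displacement, so the endpoint
#' constraint does not distort the step-length distribution. Floor of 2
#' steps; never below distance / median daily displacement would imply.
#'
#' @param kernel A [fit_movement_kernel()] result.
#' @param origin,destination Numeric `c(x, y)` positions in metres.
#' @return Integer step count.
#' @export
choose_n_steps <- function(kernel, origin, destination) {
  stopifnot(inherits(kernel, "movement_kernel"), kernel$median_step > 0)
  d <- sqrt(sum((destination - origin)^2))
  n_inv <- which.min(abs(kernel$pull$mean - d))
  # directed templates: the template's own net daily progress bounds the
  # duration (the unconstrained schedule is diffusive and would otherwise
  # overestimate the duration when the template is short)
  n_rate <- if (kernel$net_rate > 0) d / kernel$net_rate else Inf
  n <- min(n_inv, round(n_rate), length(kernel$pull$mean))
  max(2L, as.integer(n))
}

#' Simulate a fixed-endpoint trajectory from an empirical kernel
#'
#' Conditional correlated random walk between two endpoints with a fixed
#' number of daily steps, preserving the template track's geometry: at each
#' step, candidate (step length, turning angle) pairs are drawn from the
#' lag-1 conditional empirical distributions, weighted by the step-turn
#' joint lift and by a feasibility "pull" — the probability density that the
#' remaining steps can cover the remaining distance, read from the kernel's
#' pre-simulated unconstrained-walk displacement tables. The walk converges
#' when its final position lies within the kernel's tolerance
#' `eps` (half the template's median daily displacement) of the
#' destination; it is then snapped exactly onto it.
#'
#' @param kernel A `movement_kernel`.
#' @param origin,destination Numeric `c(x, y)`, metres.
#' @param n_steps Step count; default from [choose_n_steps()].
#' @param n_candidates Candidate proposals per step (the final step uses
#'   4x this many).
#' @param max_attempts Independent restarts before giving up on this kernel.
#' @return Tibble with `step` (0..n_steps), `x`, `y`; attributes
#'   `converged`, `pre_snap_miss_m`, `attempts`, `template_track_id`,
#'   `n_steps`. Non-convergence is signalled by `converged = FALSE` (callers
#'   retry with a different template, see [run_population()]).
#' @export
simulate_trajectory <- function(kernel, origin, destination, n_steps = NULL,
                                n_candidates = 50, max_attempts = 30) {
  stopifnot(inherits(kernel, "movement_kernel"))
  if (is.null(n_steps)) n_steps <- choose_n_steps(kernel, origin, destination)
  if (n_steps < 2) abort("`n_steps` must be >= 2")
  eps <- kernel$eps

  for (attempt in seq_len(max_attempts)) {
    xs <- numeric(n_steps + 1); ys <- numeric(n_steps + 1)
    xs[1] <- origin[1]; ys[1] <- origin[2]
    heading <- atan2(destination[2] - origin[2], destination[1] - origin[1])
    sb <- draw_bins(1, kernel$step_prob)
    tb <- findInterval(0, kernel$turn_breaks, all.inside = TRUE)
    ok <- TRUE

    for (t in seq_len(n_steps)) {
      k_after <- n_steps - t
      nc <- if (k_after == 0) n_candidates * 4L else n_candidates
      sb_c <- draw_bins(nc, kernel$lag1_step[sb, ])
      tb_c <- draw_bins(nc, kernel$lag1_turn[tb, ])
      st_c <- draw_from_bins(sb_c, kernel$step_breaks)
      tu_c <- draw_from_bins(tb_c, kernel$turn_breaks)
      hd_c <- heading + tu_c
      nx <- xs[t] + st_c * cos(hd_c)
      ny <- ys[t] + st_c * sin(hd_c)
      dist_c <- sqrt((nx - destination[1])^2 + (ny - destination[2])^2)
      lift <- kernel$st_lift[cbind(sb_c, tb_c)]

      if (k_after == 0) {
        feas <- dist_c <= eps
        if (!any(feas)) { ok <- FALSE; break }
        w <- lift * feas
      } else if (k_after == 1) {
        # one step will remain: weight by the empirical step-length
        # density at the distance left, so the final step stays inside the
        # kernel support (this also lets loops close through small steps)
        pb <- findInterval(dist_c, kernel$step_breaks)
        inside <- pb >= 1 & pb <= length(kernel$step_prob)
        w <- numeric(nc)
        w[inside] <- kernel$step_prob[pb[inside]] * lift[inside]
        if (sum(w) <= 0) { ok <- FALSE; break }
      } else {
        ki <- min(k_after, length(kernel$pull$mean))
        # track the unconstrained displacement schedule tightly: a narrow
        # tolerance corrects deviations while they are still recoverable,
        # which both guarantees convergence over long routes and avoids the
        # step-length distortion of late forced corrections
        sd_eff <- max(kernel$pull$sd[ki] * 0.1, kernel$median_step / 2)
        lw <- dnorm(dist_c, kernel$pull$mean[ki], sd_eff, log = TRUE)
        w <- exp(lw - max(lw)) * lift
      }
      if (!any(is.finite(w)) || sum(w) <= 0) { ok <- FALSE; break }
      pick <- sample.int(nc, 1, prob = w)
      xs[t + 1] <- nx[pick]; ys[t + 1] <- ny[pick]
      heading <- hd_c[pick]
      sb <- sb_c[pick]; tb <- tb_c[pick]
    }

    if (ok) {
      miss <- sqrt((xs[n_steps + 1] - destination[1])^2 +
                   (ys[n_steps + 1] - destination[2])^2)
      xs[n_steps + 1] <- destination[1]
      ys[n_steps + 1] <- destination[2]
      out <- tibble(step = 0:n_steps, x = xs, y = ys)
      attr(out, "converged") <- TRUE
      attr(out, "pre_snap_miss_m") <- miss
      attr(out, "attempts") <- attempt
      attr(out, "template_track_id") <- kernel$source_track_id
      attr(out, "n_steps") <- n_steps
      class(out) <- c("sim_trajectory", class(out))
      return(out)
    }
  }
  out <- tibble(step = integer(), x = numeric(), y = numeric())
  attr(out, "converged") <- FALSE
  attr(out, "attempts") <- max_attempts
  attr(out, "template_track_id") <- kernel$source_track_id
  class(out) <- c("sim_trajectory", class(out))
  out
}

#' Simulate trajectories for a whole assigned population
#'
#' For each origin-destination assignment, a template kernel is selected
#' uniformly at random (with replacement); if the trajectory generator fails
#' to converge with that template, another is drawn, up to a global attempt
#' cap. Per-individual RNG substreams keep the output invariant to
#' evaluation order and reproducible under a fixed upstream seed.
#'
#' @param assignments Tibble from [assign_individuals()].
#' @param kernels List of `movement_kernel`s.
#' @param grid A `hex_grid` (maps cell ids to centroids).
#' @param max_attempts Global per-individual template draws before erroring.
#' @param n_candidates Passed to [simulate_trajectory()].
#' @return Tibble with `individual_id`, `template_track_id`, `origin_cell`,
#'   `dest_cell`, `step`, `x`, `y`; attribute `retry_log` (tibble of
#'   per-individual template attempts).
#' @export
run_population <- function(assignments, kernels, grid,
                           max_attempts = 100, n_candidates = 50) {
  stopifnot(length(kernels) >= 1, nrow(assignments) >= 1)
  base <- sample.int(2147483646L, 1)
  oi <- match(assignments$origin_cell, grid$cell_id)
  di <- match(assignments$dest_cell, grid$cell_id)
  if (anyNA(oi) || anyNA(di)) abort("assignment references a cell not in the grid")

  res <- vector("list", nrow(assignments))
  log <- vector("list", nrow(assignments))
  for (i in seq_len(nrow(assignments))) {
    set.seed(substream_seed(base, i))
    origin <- c(grid$x[oi[i]], grid$y[oi[i]])
    dest <- c(grid$x[di[i]], grid$y[di[i]])
    tries <- 0; traj <- NULL
    while (tries < max_attempts) {
      kid <- sample.int(length(kernels), 1)
      traj <- simulate_trajectory(kernels[[kid]], origin, dest,
                                  n_candidates = n_candidates,
                                  max_attempts = 5)
      tries <- tries + 1
      if (attr(traj, "converged")) break
    }
    if (!attr(traj, "converged")) {
      abort(sprintf(
        "individual %s: no template converged after %d attempts (origin %d, dest %d, distance %.0f m)",
        assignments$individual_id[i], max_attempts,
        assignments$origin_cell[i], assignments$dest_cell[i],
        sqrt(sum((dest - origin)^2))))
    }
    res[[i]] <- traj %>%
      mutate(individual_id = assignments$individual_id[i],
             template_track_id = attr(traj, "template_track_id"),
             origin_cell = assignments$origin_cell[i],
             dest_cell = assignments$dest_cell[i]) %>%
      select("individual_id", "template_track_id", "origin_cell",
             "dest_cell", "step", "x", "y")
    log[[i]] <- tibble(individual_id = assignments$individual_id[i],
                       template_draws = tries)
  }
  out <- bind_rows(res)
  attr(out, "retry_log") <- bind_rows(log)
  out
}
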