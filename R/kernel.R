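#' Fit an empirical movement kernel from a daily-thinned track
#'
#' Extracts the binned empirical distributions that parameterize the
#' trajectory generator: daily step lengths (Freedman-Diaconis bins),
#' turning angles (36 fixed bins on (-pi, pi]), their lag-1
#' autocorrelation structure (conditional bin-transition matrices), and the
#' step-turn joint distribution. Also pre-simulates unconstrained
#' correlated walks from the fitted kernel to tabulate the k-step
#' displacement distribution used as the endpoint "pull" during conditional
#' simulation (this pre-simulation runs under a seed derived from the track
#' id, so fitting is deterministic).
#'
#' @param track Daily-thinned track tibble for one individual with
#'   projected `x`/`y` (metres); at least 10 steps.
#' @param n_presim Number of unconstrained walks for the pull tables.
#' @param max_horizon Longest trajectory (steps) the pull tables support.
#' @return Object of class `movement_kernel`.
#' @export
fit_movement_kernel <- function(track, n_presim = 500, max_horizon = 120) {
  track <- project_tracks(track)
  dx <- diff(track$x); dy <- diff(track$y)
  steps <- sqrt(dx^2 + dy^2)
  if (length(steps) < 10) {
    abort(sprintf("track must have >= 10 steps after thinning, got %d", length(steps)))
  }
  headings <- atan2(dy, dx)
  turns <- wrap_angle(diff(headings))

  # step bins: Freedman-Diaconis width, padded so all observations fall inside
  h <- 2 * stats::IQR(steps) / length(steps)^(1 / 3)
  if (!is.finite(h) || h <= 0) h <- max(diff(range(steps)) / 10, 1)
  lo <- max(0, min(steps) - h / 2)
  k <- max(3, ceiling((max(steps) - lo) / h + 1))
  step_breaks <- lo + (0:k) * h
  turn_breaks <- seq(-pi, pi, length.out = 37)

  sbin <- findInterval(steps, step_breaks, all.inside = TRUE)
  tbin <- findInterval(turns, turn_breaks, all.inside = TRUE)
  ns <- length(step_breaks) - 1
  nt <- 36

  tab <- function(idx, n) {
    p <- tabulate(idx, n)
    p / sum(p)
  }
  joint <- function(i1, i2, n1, n2) {
    m <- matrix(0, n1, n2)
    for (q in seq_along(i1)) m[i1[q], i2[q]] <- m[i1[q], i2[q]] + 1
    m / sum(m)
  }
  cond <- function(jmat) {
    rs <- rowSums(jmat)
    out <- jmat / ifelse(rs > 0, rs, 1)
    out[rs == 0, ] <- rep(colSums(jmat) / sum(jmat), each = sum(rs == 0))
    out
  }

  step_prob <- tab(sbin, ns)
  turn_prob <- tab(tbin, nt)
  lag1_step <- cond(joint(sbin[-length(sbin)], sbin[-1], ns, ns))
  lag1_turn <- cond(joint(tbin[-length(tbin)], tbin[-1], nt, nt))
  nst <- min(length(sbin), length(tbin))
  st_joint <- joint(sbin[seq_len(nst)], tbin[seq_len(nst)], ns, nt)
  # likelihood-ratio lift of the joint over independence, lightly smoothed
  alpha <- 1 / (nst * ns * nt)
  st_lift <- (st_joint + alpha) / (outer(step_prob, turn_prob) + alpha)

  kern <- structure(
    list(
      source_track_id = track$individual_id[1],
      n_steps_emp = length(steps),
      step_breaks = step_breaks, step_prob = step_prob,
      turn_breaks = turn_breaks, turn_prob = turn_prob,
      lag1_step = lag1_step, lag1_turn = lag1_turn,
      st_lift = st_lift,
      step_obs = steps, turn_obs = turns,
      mean_step = mean(steps),
      median_step = median(steps),
      # net migratory progress per day of the template (directed legs have
      # rate close to the mean step; tortuous tracks much less)
      net_rate = sqrt((track$x[nrow(track)] - track$x[1])^2 +
                        (track$y[nrow(track)] - track$y[1])^2) / length(steps),
      circ_mean_turn = atan2(mean(sin(turns)), mean(cos(turns))),
      eps = median(steps) / 2
    ),
    class = "movement_kernel"
  )
  kern$pull <- presim_pull(kern, n_presim, max_horizon)
  kern
}

# Empirical moments of the histogram representation (bin-midpoint weighted).
kernel_moments <- function(kern) {
  mids <- (head(kern$step_breaks, -1) + tail(kern$step_breaks, -1)) / 2
  tmids <- (head(kern$turn_breaks, -1) + tail(kern$turn_breaks, -1)) / 2
  list(
    mean_step = sum(mids * kern$step_prob),
    circ_mean_turn = atan2(sum(sin(tmids) * kern$turn_prob),
                           sum(cos(tmids) * kern$turn_prob))
  )
}

# draw n bin indices from probability vector p
draw_bins <- function(n, p) {
  sample.int(length(p), n, replace = TRUE, prob = p)
}

# continuous values uniform within the bins picked
draw_from_bins <- function(bins, breaks) {
  runif(length(bins), breaks[bins], breaks[bins + 1])
}

# Tabulate mean/sd of displacement after k unconstrained steps, k = 1..K,
# from n walks driven by the kernel's lag-1 conditionals.
presim_pull <- function(kern, n, K) {
  with_seed(substream_seed(sum(utf8ToInt(paste0("pull", kern$source_track_id))), 1), {
    x <- numeric(n); y <- numeric(n); headv <- runif(n, -pi, pi)
    sb <- draw_bins(n, kern$step_prob)
    tb <- draw_bins(n, kern$turn_prob)
    pm <- numeric(K); ps <- numeric(K)
    cond_step <- function(bins, cmat) {
      out <- integer(length(bins))
      for (b in unique(bins)) {
        idx <- which(bins == b)
        out[idx] <- draw_bins(length(idx), cmat[b, ])
      }
      out
    }
    for (k in seq_len(K)) {
      sb <- cond_step(sb, kern$lag1_step)
      tb <- cond_step(tb, kern$lag1_turn)
      st <- draw_from_bins(sb, kern$step_breaks)
      tu <- draw_from_bins(tb, kern$turn_breaks)
      headv <- headv + tu
      x <- x + st * cos(headv)
      y <- y + st * sin(headv)
      disp <- sqrt(x^2 + y^2)
      pm[k] <- mean(disp)
      ps[k] <- max(sd(disp), kern$median_step / 4)
    }
    list(mean = pm, sd = ps)
  })
}

#' @export
print.movement_kernel <- function(x, ...) {
  cat(sprintf(
    "Movement kernel from '%s': %d steps, mean step %.0f m, median %.0f m, circ. mean turn %.3f rad\n",
    x$source_track_id, x$n_steps_emp, x$mean_step, x$median_step, x$circ_mean_turn))
  invisible(x)
}
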