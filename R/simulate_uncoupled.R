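#' Simulate an uncoupled population of non-leaky integrate-and-fire neurons
#'
#' Each of `n` identical neurons independently receives the current
#' \eqn{I_i(t) = \mu(t) + \sigma(t)\,\xi_i(t)} with unit-magnitude Gaussian
#' white noise \eqn{\xi_i}, and integrates it without leak:
#' \eqn{\tau\,dv/dt = I}.  Spikes are emitted at \eqn{v \ge \theta} and the
#' potential is reset to `v0`.  Two noise structures are supported:
#' constant VMR (`sigma2(t) = beta * mu(t)`, the optimal structure for
#' instantaneous population tracking) and constant variance
#' (`sigma2(t) = sigma2`).
#'
#' @param n Number of neurons.
#' @param mu Mean input current: a scalar or a function of time (must stay
#'   non-negative in constant-VMR mode).
#' @param noise `"constant_vmr"` or `"constant_sigma"`.
#' @param beta VMR \eqn{\beta = \sigma^2/\mu} used in constant-VMR mode.
#' @param sigma2 Variance rate used in constant-sigma mode.
#' @param theta,tau,v0 Neuron parameters.
#' @param duration,dt Simulated time span and Euler step.
#' @param seed Optional integer seed.
#' @param init Initial potentials: `"stationary"` (inverse-CDF sample of
#'   the stationary density at the initial parameters), `"uniform"` on
#'   `[v0, theta)`, or `"reset"` (all at `v0`).
#' @param reflecting_barrier Clamp `v` at `v0` from below.
#' @param carry_overshoot If `TRUE`, reset to `v0 + (v - theta)` so that
#'   each spike absorbs exactly `theta - v0` of integrated drive; this
#'   removes the O(dt) discretization bias of the firing rate.  Default
#'   `FALSE` (plain reset to `v0`).
#' @param record_events Keep the full (neuron, time) spike table.
#' @param snapshot_times Times at which to store membrane snapshots.
#' @return An object of class `"uncoupled_sim"`: per-step spike `counts`,
#'   optional `events` data frame, membrane `snapshots`, and the
#'   configuration.
#' @examples
#' sim <- run_uncoupled(500, mu = 1, beta = 1, duration = 10, dt = 0.01,
#'                      seed = 1)
#' mean(sim$counts) / (500 * sim$dt)  # ~ mu / (theta * tau) = 1
#' @export
run_uncoupled <- function(n, mu, noise = c("constant_vmr", "constant_sigma"),
                          beta = 1, sigma2 = 1,
                          theta = 1, tau = 1, v0 = 0,
                          duration, dt = 0.002, seed = NULL,
                          init = c("stationary", "uniform", "reset"),
                          reflecting_barrier = FALSE, carry_overshoot = FALSE,
                          record_events = TRUE, snapshot_times = numeric()) {
  noise <- match.arg(noise)
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  mu_fun <- if (is.function(mu)) mu else function(t) mu
  sig2_at <- function(t) {
    m <- mu_fun(t)
    if (noise == "constant_vmr") {
      if (m < 0) stop("constant-VMR mode requires mu(t) >= 0 (sigma2 = beta * mu)")
      beta * m
    } else sigma2
  }
  mu0 <- mu_fun(0)
  v <- switch(init,
    stationary = {
      s20 <- sig2_at(0)
      if (mu0 > 0 && s20 > 0)
        v0 + sample_stationary_v(n, mu0, s20, theta - v0, tau)
      else stats::runif(n, v0, theta)
    },
    uniform = stats::runif(n, v0, theta),
    reset = rep(v0, n))

  nsteps <- max(1L, round(duration / dt))
  counts <- integer(nsteps)
  ev <- if (record_events) vector("list", nsteps) else NULL
  snaps <- list()
  snap_q <- sort(snapshot_times)
  sqdt <- sqrt(dt)
  for (s in seq_len(nsteps)) {
    t0 <- (s - 1L) * dt
    m <- mu_fun(t0)
    s2 <- sig2_at(t0)
    v <- v + (m * dt + sqrt(s2) * sqdt * stats::rnorm(n)) / tau
    fired <- v >= theta
    nf <- sum(fired)
    counts[s] <- nf
    if (nf) {
      if (record_events) ev[[s]] <- which(fired)
      v[fired] <- if (carry_overshoot) v0 + (v[fired] - theta) else v0
    }
    if (reflecting_barrier) v[v < v0] <- v0
    while (length(snap_q) && snap_q[1] <= s * dt + 1e-12) {
      snaps[[length(snaps) + 1L]] <- list(t = snap_q[1], v = v)
      snap_q <- snap_q[-1]
    }
  }
  events <- NULL
  if (record_events) {
    lens <- lengths(ev)
    events <- data.frame(
      population = "U",
      neuron = unlist(ev, use.names = FALSE),
      time = rep(seq_len(nsteps) * dt, lens))
    if (is.null(events$neuron)) events <- events[0, ]
  }
  structure(list(events = events, counts = counts, n = n,
                 dt = dt, duration = nsteps * dt, snapshots = snaps,
                 theta = theta, tau = tau, v0 = v0, noise = noise,
                 v_final = v),
            class = "uncoupled_sim")
}

#' @export
print.uncoupled_sim <- function(x, ...) {
  cat(sprintf("<uncoupled_sim> n = %d, T = %g (dt = %g), %d spikes (mean rate %.4g)\n",
              x$n, x$duration, x$dt, sum(x$counts),
              sum(x$counts) / (x$n * x$duration)))
  invisible(x)
}

#' Population rate trace from per-step spike counts
#'
#' @param sim An `"uncoupled_sim"` or `"ei_sim"` object.
#' @param bin Bin width in time units.
#' @param population For network simulations, which population's counts to
#'   use.
#' @return data.frame with bin centers `t` and rate `r` in spikes per
#'   neuron per time unit.
#' @export
rate_trace <- function(sim, bin = 0.5, population = "E") {
  if (inherits(sim, "ei_sim")) {
    counts <- sim$counts[, population]
    n <- sim$sizes[[population]]
  } else {
    counts <- sim$counts
    n <- sim$n
  }
  steps_per_bin <- max(1L, round(bin / sim$dt))
  nb <- floor(length(counts) / steps_per_bin)
  idx <- rep(seq_len(nb), each = steps_per_bin)
  csum <- tapply(counts[seq_along(idx)], idx, sum)
  data.frame(t = (seq_len(nb) - 0.5) * steps_per_bin * sim$dt,
             r = as.numeric(csum) / (n * steps_per_bin * sim$dt))
}

#' 90% rise time of a step response
#'
#' Given a rate trace and the step onset, finds the first time after the
#' step at which the (lightly smoothed) rate reaches
#' `baseline + frac * (target - baseline)`, where the baseline and target
#' levels are measured from the trace before the step and at the end of the
#' trace.
#'
#' @param trace data.frame with columns `t` and `r`.
#' @param t_step Step onset time.
#' @param frac Fraction of the level change (default 0.9).
#' @param smooth Half-width (in bins) of the moving-average smoother.
#' @param settle Fraction of the post-step span used to estimate the new
#'   steady level (from the end of the trace).
#' @return Rise time in time units (time after `t_step`).
#' @export
rise_time <- function(trace, t_step, frac = 0.9, smooth = 2L, settle = 0.25) {
  r <- trace$r
  if (smooth > 0) {
    k <- 2L * smooth + 1L
    r <- stats::filter(r, rep(1 / k, k), sides = 2)
    r[is.na(r)] <- trace$r[is.na(r)]
  }
  pre <- r[trace$t < t_step]
  post <- r[trace$t >= t_step]
  tpost <- trace$t[trace$t >= t_step]
  if (!length(pre) || !length(post)) stop("step time outside the trace")
  base <- mean(pre)
  tail_n <- max(1L, round(settle * length(post)))
  target <- mean(post[(length(post) - tail_n + 1L):length(post)])
  thresh <- base + frac * (target - base)
  hit <- if (target >= base) which(post >= thresh) else which(post <= thresh)
  if (!length(hit)) return(NA_real_)
  tpost[hit[1L]] - t_step
}
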