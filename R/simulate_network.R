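#' Feedforward drive specification
#'
#' The external input to every neuron of population `a` is
#' \eqn{F_i^a(t) = N f_a \mu_F(t) + \sigma_{aF}(t)\,\xi_i^{aF}(t)} with
#' unit-magnitude Gaussian white noise independent across neurons.  The
#' noise structure is set by `vmr_mode`:
#' * `"poisson_like"` (alias `"constant_beta"`): \eqn{\sigma_{aF}^2 =
#'   \beta_F\,\mu_F(t)}, the structure inherited from upstream Poisson
#'   spiking, keeping the feedforward VMR constant in time;
#' * `"constant_sigma"`: \eqn{\sigma_{aF}^2} fixed at `sigma2_F`.
#'
#' @param mu_F Signal mean scale: a non-negative scalar or function of time.
#' @param f Feedforward gains `c(E = , I = )`; defaults to the network's.
#' @param vmr_mode Noise structure (see above).
#' @param beta_F Feedforward VMR for the Poisson-like mode.
#' @param sigma2_F Fixed variance rate for the constant-sigma mode.
#' @return An object of class `"ff_drive"`.
#' @export
feedforward_drive <- function(mu_F,
                              f = NULL,
                              vmr_mode = c("poisson_like", "constant_beta",
                                           "constant_sigma"),
                              beta_F = 0.1, sigma2_F = NULL) {
  vmr_mode <- match.arg(vmr_mode)
  if (vmr_mode == "constant_beta") vmr_mode <- "poisson_like"
  if (vmr_mode == "constant_sigma") {
    if (is.null(sigma2_F) || sigma2_F < 0)
      stop("constant-sigma mode needs a non-negative 'sigma2_F'")
  }
  mu_fun <- if (is.function(mu_F)) mu_F else function(t) mu_F
  structure(list(mu_F = mu_fun, f = f, vmr_mode = vmr_mode,
                 beta_F = beta_F, sigma2_F = sigma2_F),
            class = "ff_drive")
}

drive_sigma2 <- function(drive, mu_t) {
  if (drive$vmr_mode == "poisson_like") {
    if (mu_t < 0) stop("Poisson-like drive requires mu_F(t) >= 0")
    drive$beta_F * mu_t
  } else drive$sigma2_F
}

#' Simulate a homogeneous E-I balanced network
#'
#' Time-stepped simulation of the two-population recurrent network.  Per
#' step, each neuron receives the feedforward current of its population's
#' [feedforward_drive()] plus the recurrent current
#' \eqn{R_i^a(t) = \sum_b \sum_j J_{ij}^{ab} \sum_k
#' \frac{1}{\tau_{b,s}} e^{-(t - t_{j,k})/\tau_{b,s}}},
#' implemented as per-neuron exponential synaptic traces with exact decay
#' (the unit-integral kernel delivers total charge \eqn{J_{ij}^{ab}} per
#' spike).  Membrane potentials follow the non-leaky Euler update; neurons
#' crossing threshold are reset to `v0` once per step.
#'
#' @param object A [balanced_network()].
#' @param nsim Number of independent runs (a list is returned for
#'   `nsim > 1`).
#' @param seed Optional integer seed.
#' @param drive A [feedforward_drive()].
#' @param duration Simulated time.
#' @param dt Integration step; default `min(tau_s) / 20`.  A warning is
#'   issued above `min(tau_m, tau_s) / 10`.
#' @param connectivity Optional pre-sampled [sample_connectivity()] result
#'   (otherwise one realization is drawn per run).
#' @param record_events Character vector of population labels whose
#'   (neuron, time) spike tables are kept.
#' @param snapshot_times Times at which to store E-population membrane
#'   snapshots.
#' @param init Initial potentials: `"uniform"` on `[v0, theta)` or
#'   `"reset"`.
#' @param warn_unbalanced Warn when the balance condition fails.
#' @param ... Unused.
#' @return An `"ei_sim"` object: per-step spike `counts` (matrix with E/I
#'   columns), `events`, `snapshots`, sizes and configuration.
#' @export
simulate.balanced_network <- function(object, nsim = 1, seed = NULL, drive,
                                      duration, dt = NULL,
                                      connectivity = NULL,
                                      record_events = "E",
                                      snapshot_times = numeric(),
                                      init = c("uniform", "reset"),
                                      warn_unbalanced = TRUE, ...) {
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  if (warn_unbalanced && !check_balance_condition(object)$balanced)
    warning("balance condition does not hold; expect pathological or silent firing")
  if (is.null(dt)) dt <- min(object$tau_s) / 20
  if (dt > min(object$tau_m, object$tau_s) / 10)
    warning("dt exceeds min(tau_m, tau_s)/10; dynamics may be under-resolved")
  if (nsim > 1) {
    return(lapply(seq_len(nsim), function(k)
      simulate.balanced_network(object, nsim = 1, seed = NULL, drive = drive,
                                duration = duration, dt = dt,
                                connectivity = connectivity,
                                record_events = record_events,
                                snapshot_times = snapshot_times, init = init,
                                warn_unbalanced = FALSE)))
  }
  conn <- if (is.null(connectivity)) sample_connectivity(object) else connectivity
  f <- if (!is.null(drive$f)) as_named(drive$f, POPS, "f") else object$f

  net_step_loop(object, conn$J, drive, f, duration, dt, record_events,
                snapshot_times, init)
}

net_step_loop <- function(net, J, drive, f, duration, dt, record_events,
                          snapshot_times, init) {
  nE <- net$sizes[["E"]]; nI <- net$sizes[["I"]]
  theta <- net$theta; v0 <- net$v0
  vE <- if (init == "uniform") stats::runif(nE, v0, theta) else rep(v0, nE)
  vI <- if (init == "uniform") stats::runif(nI, v0, theta) else rep(v0, nI)
  # synaptic traces: s[[post]][[pre]]
  s <- list(E = list(E = numeric(nE), I = numeric(nE)),
            I = list(E = numeric(nI), I = numeric(nI)))
  decay <- exp(-dt / net$tau_s)
  kick <- 1 / net$tau_s                   # unit-integral kernel height
  nsteps <- max(1L, round(duration / dt))
  counts <- matrix(0L, nsteps, 2L, dimnames = list(NULL, POPS))
  evE <- if ("E" %in% record_events) vector("list", nsteps) else NULL
  evI <- if ("I" %in% record_events) vector("list", nsteps) else NULL
  snaps <- list(); snap_q <- sort(snapshot_times)
  sqdt <- sqrt(dt)
  patho <- 0L; patho_warned <- FALSE
  NfE <- net$N * f[["E"]]; NfI <- net$N * f[["I"]]

  for (step in seq_len(nsteps)) {
    t0 <- (step - 1L) * dt
    mu_t <- drive$mu_F(t0)
    s2 <- drive_sigma2(drive, mu_t)
    if (!is.finite(mu_t) || !is.finite(s2))
      stop("non-finite feedforward input at t = ", t0)
    sig <- sqrt(s2) * sqdt
    # total input N·(f_a mu_F + sum_b J-weighted traces) + white noise:
    # the stored weights are j_ab/N, so the N factor restores the O(N)
    # feedforward/recurrent bookkeeping that the balance cancels to O(1)
    vE <- vE + ((NfE * mu_t + net$N * (s[["E"]]$E + s[["E"]]$I)) * dt +
                  sig * stats::rnorm(nE)) / net$tau_m[["E"]]
    vI <- vI + ((NfI * mu_t + net$N * (s[["I"]]$E + s[["I"]]$I)) * dt +
                  sig * stats::rnorm(nI)) / net$tau_m[["I"]]
    fE <- vE >= theta; fI <- vI >= theta
    cE <- sum(fE); cI <- sum(fI)
    counts[step, ] <- c(cE, cI)
    if (cE) { if (!is.null(evE)) evE[[step]] <- which(fE); vE[fE] <- v0 }
    if (cI) { if (!is.null(evI)) evI[[step]] <- which(fI); vI[fI] <- v0 }
    if (net$reflecting_barrier) { vE[vE < v0] <- v0; vI[vI < v0] <- v0 }
    # synaptic traces: exact exponential decay + incoming weighted spikes
    s[["E"]]$E <- s[["E"]]$E * decay[["E"]]
    s[["E"]]$I <- s[["E"]]$I * decay[["I"]]
    s[["I"]]$E <- s[["I"]]$E * decay[["E"]]
    s[["I"]]$I <- s[["I"]]$I * decay[["I"]]
    if (cE) {
      xe <- as.numeric(fE)
      s[["E"]]$E <- s[["E"]]$E + as.numeric(J$EE %*% xe) * kick[["E"]]
      s[["I"]]$E <- s[["I"]]$E + as.numeric(J$IE %*% xe) * kick[["E"]]
    }
    if (cI) {
      xi <- as.numeric(fI)
      s[["E"]]$I <- s[["E"]]$I + as.numeric(J$EI %*% xi) * kick[["I"]]
      s[["I"]]$I <- s[["I"]]$I + as.numeric(J$II %*% xi) * kick[["I"]]
    }
    patho <- if (cE + cI >= 0.99 * (nE + nI)) patho + 1L else 0L
    if (patho > 100L && !patho_warned) {
      warning("pathological firing: every neuron spiking each step for > 100 steps (balance violated)")
      patho_warned <- TRUE
    }
    while (length(snap_q) && snap_q[1] <= step * dt + 1e-12) {
      snaps[[length(snaps) + 1L]] <- list(t = snap_q[1], v = vE)
      snap_q <- snap_q[-1]
    }
  }
  events <- collect_events(list(E = evE, I = evI), dt)
  structure(list(events = events, counts = counts,
                 sizes = net$sizes, dt = dt, duration = nsteps * dt,
                 snapshots = snaps, theta = theta, net = net),
            class = "ei_sim")
}

collect_events <- function(ev_by_pop, dt) {
  pieces <- list()
  for (pop in names(ev_by_pop)) {
    ev <- ev_by_pop[[pop]]
    if (is.null(ev)) next
    lens <- lengths(ev)
    if (!sum(lens)) next
    pieces[[pop]] <- data.frame(
      population = pop,
      neuron = unlist(ev, use.names = FALSE),
      time = rep(seq_along(ev) * dt, lens))
  }
  if (!length(pieces))
    return(data.frame(population = character(), neuron = integer(),
                      time = numeric()))
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$time), , drop = FALSE]
}

#' @export
print.ei_sim <- function(x, ...) {
  cat(sprintf("<ei_sim> T = %g (dt = %g); rates: E %.4g, I %.4g spikes/neuron/time\n",
              x$duration, x$dt,
              sum(x$counts[, "E"]) / (x$sizes[["E"]] * x$duration),
              sum(x$counts[, "I"]) / (x$sizes[["I"]] * x$duration)))
  invisible(x)
}

#' @export
plot.ei_sim <- function(x, bin = 1, ...) {
  tr <- rate_trace(x, bin = bin, population = "E")
  graphics::plot(tr$t, tr$r, type = "l", xlab = "time",
                 ylab = "E population rate", ...)
  invisible(x)
}
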