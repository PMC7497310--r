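#' Simulate the spatial balanced network with an event-camera front end
#'
#' Full pipeline: the stimulus is rendered onto the pixel grid each step,
#' the pixel layer integrates it (non-leaky, threshold `theta_F`), pixel
#' spikes are delivered to the balanced layer through the sampled Gaussian
#' feedforward connectivity with synaptic constant `tau_s["F"]`, and the
#' E/I populations evolve exactly as in the homogeneous simulator but with
#' spatially local recurrent connectivity.
#'
#' @param object A [spatial_network()].
#' @param nsim Number of runs (list returned when > 1).
#' @param seed Optional seed.
#' @param stimulus A [disc_stimulus()] (or a function `f(t)` giving the
#'   pixel intensity vector directly).
#' @param duration,dt Simulated span and step; `dt` defaults to
#'   `min(tau_s) / 20`.
#' @param connectivity Optional pre-sampled [sample_spatial_network()].
#' @param record_events Populations whose spike tables to keep (default E
#'   and the pixel layer F, the two layers compared by the decoders).
#' @param init `"uniform"` (staggered potentials) or `"reset"`.
#' @param warn_unbalanced Warn when [check_spatial_balance()] fails.
#' @param ... Unused.
#' @return A `"spatial_sim"` object (also `"ei_sim"`): spike `events`
#'   (populations E/I/F), per-step `counts`, `sizes`, `layouts`.
#' @export
simulate.spatial_network <- function(object, nsim = 1, seed = NULL, stimulus,
                                     duration, dt = NULL,
                                     connectivity = NULL,
                                     record_events = c("E", "F"),
                                     init = c("uniform", "reset"),
                                     warn_unbalanced = TRUE, ...) {
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  if (warn_unbalanced && !check_spatial_balance(object)$balanced)
    warning("spatial balance conditions do not hold")
  if (is.null(dt)) dt <- min(object$tau_s) / 20
  if (nsim > 1) {
    return(lapply(seq_len(nsim), function(k)
      simulate.spatial_network(object, nsim = 1, seed = NULL,
                               stimulus = stimulus, duration = duration,
                               dt = dt, connectivity = connectivity,
                               record_events = record_events, init = init,
                               warn_unbalanced = FALSE)))
  }
  conn <- if (is.null(connectivity)) sample_spatial_network(object)
          else connectivity
  J <- conn$J
  net <- object
  nE <- net$sizes[["E"]]; nI <- net$sizes[["I"]]; nF <- net$sizes[["F"]]
  theta <- net$theta; thF <- net$theta_F
  layF <- net$layouts$F
  field_fun <- if (is.function(stimulus)) stimulus else
    function(t) render_stimulus(stimulus, t, layF, noise = TRUE,
                                torus = net$torus)
  vE <- if (init == "uniform") stats::runif(nE, 0, theta) else numeric(nE)
  vI <- if (init == "uniform") stats::runif(nI, 0, theta) else numeric(nI)
  vF <- if (init == "uniform") stats::runif(nF, 0, thF) else numeric(nF)
  s <- list(E = list(E = numeric(nE), I = numeric(nE), F = numeric(nE)),
            I = list(E = numeric(nI), I = numeric(nI), F = numeric(nI)))
  decay <- exp(-dt / net$tau_s)
  kick <- 1 / net$tau_s
  nsteps <- max(1L, round(duration / dt))
  counts <- matrix(0L, nsteps, 3L, dimnames = list(NULL, SPAT_PRE))
  ev <- list(E = if ("E" %in% record_events) vector("list", nsteps),
             I = if ("I" %in% record_events) vector("list", nsteps),
             F = if ("F" %in% record_events) vector("list", nsteps))
  patho <- 0L; patho_warned <- FALSE

  for (step in seq_len(nsteps)) {
    t0 <- (step - 1L) * dt
    # pixel layer: deterministic luminance integration
    I_F <- field_fun(t0)
    if (any(!is.finite(I_F))) stop("non-finite stimulus intensity at t = ", t0)
    vF <- vF + I_F * dt / net$tau_F
    fF <- vF >= thF
    cF <- sum(fF)
    if (cF) { if (!is.null(ev$F)) ev$F[[step]] <- which(fF); vF[fF] <- 0 }
    # balanced layer: recurrent + feedforward synaptic currents; stored
    # weights are j_ab/N, so the N factor restores the O(N) input
    # bookkeeping that the balance cancels to O(1)
    vE <- vE + net$N * (s[["E"]]$E + s[["E"]]$I + s[["E"]]$F) * dt /
      net$tau_m[["E"]]
    vI <- vI + net$N * (s[["I"]]$E + s[["I"]]$I + s[["I"]]$F) * dt /
      net$tau_m[["I"]]
    fE <- vE >= theta; fI <- vI >= theta
    cE <- sum(fE); cI <- sum(fI)
    counts[step, ] <- c(cE, cI, cF)
    if (cE) { if (!is.null(ev$E)) ev$E[[step]] <- which(fE); vE[fE] <- 0 }
    if (cI) { if (!is.null(ev$I)) ev$I[[step]] <- which(fI); vI[fI] <- 0 }
    if (net$reflecting_barrier) { vE[vE < 0] <- 0; vI[vI < 0] <- 0 }
    for (a in POPS) for (b in SPAT_PRE)
      s[[a]][[b]] <- s[[a]][[b]] * decay[[b]]
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
    if (cF) {
      xf <- as.numeric(fF)
      s[["E"]]$F <- s[["E"]]$F + as.numeric(J$EF %*% xf) * kick[["F"]]
      s[["I"]]$F <- s[["I"]]$F + as.numeric(J$IF %*% xf) * kick[["F"]]
    }
    patho <- if (cE + cI >= 0.99 * (nE + nI)) patho + 1L else 0L
    if (patho > 100L && !patho_warned) {
      warning("pathological firing in the balanced layer (balance violated)")
      patho_warned <- TRUE
    }
  }
  events <- collect_events(ev[!vapply(ev, is.null, logical(1))], dt)
  structure(list(events = events, counts = counts, sizes = net$sizes,
                 layouts = net$layouts, dt = dt, duration = nsteps * dt,
                 theta = theta, net = net),
            class = c("spatial_sim", "ei_sim"))
}

#' Time-averaged spatial rate map
#'
#' @param sim A `"spatial_sim"`.
#' @param population `"E"`, `"I"` or `"F"`.
#' @param t_range Time window `c(from, to)`; default the full run.
#' @return Matrix (grid) of rates in spikes per neuron per time unit.
#' @export
rate_map <- function(sim, population = "E", t_range = NULL) {
  lay <- sim$layouts[[population]]
  ev <- sim$events[sim$events$population == population, ]
  if (!is.null(t_range))
    ev <- ev[ev$time > t_range[1] & ev$time <= t_range[2], ]
  span <- if (is.null(t_range)) sim$duration else diff(t_range)
  cnt <- tabulate(ev$neuron, nbins = nrow(lay))
  matrix(cnt / span, attr(lay, "nx"), attr(lay, "ny"))
}
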