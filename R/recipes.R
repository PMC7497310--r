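#' Canned experiment recipes
#'
#' Returns a complete, validated configuration for one of the named preset
#' experiments.  At `scale = 1` every recipe carries its reference
#' parameter set verbatim; `scale` shrinks the network (total size for the
#' homogeneous recipes, per-axis grid dimensions by `sqrt(scale)` for the
#' spatial ones) while connection strengths stay `j / N` with the new `N`.
#'
#' Available recipes:
#' * `fig2a` — uncoupled population (N = 2500, theta = tau = 1), constant
#'   unit VMR, input mean stepping 1 to 5 at t = 5; membrane snapshot and
#'   KS statistic against the stationary density.
#' * `fig2b` — same input but constant noise variance (sigma^2 = 1)
#'   instead of constant VMR, the slow-tracking control.
#' * `fig3` — homogeneous E-I network (N = 10^4, q_I = 0.2, p = 0.25,
#'   theta = 15, tau_E = 15, tau_I = 10, tau_Es = 6, tau_Is = 5, f = (3, 2),
#'   j = (0.25, -1, 0.4, -1)) tracking a sinusoidal drive centered at 0.1
#'   with amplitude 0.05 and constant feedforward VMR 0.1.
#' * `fig5a` — spatial network (50x50 pixel layer, 80x80 E, 40x40 I, the
#'   local-connectivity parameter set) with a disc at (0.25, 0.5), radius
#'   0.05, magnitude stepping 1.5 to 15 at t = 75, plus background noise.
#' * `fig5b` — as `fig5a` with sinusoidal magnitude
#'   mu(t) = 30 sin(1.5 * 2 pi t / T) + 30.
#' * `fig5cd` — disc of magnitude 10 moving linearly across the field.
#' * `fig5ef` — the same disc moving counterclockwise on a circle.
#' * `fig6a` — one point of the temporal-lag sweep: the `fig5b` task at a
#'   chosen signal period, reporting the response phase lag.
#' * `fig6b` — one point of the spatial-lag sweep: the `fig5ef` task at a
#'   chosen revolution period, reporting the spatial phase lag.
#'
#' @param name Recipe name (see above).
#' @param scale Size scale factor in (0, 1].
#' @param seed Integer seed forwarded to the run.
#' @param period Signal / revolution period for `fig6a` / `fig6b`.
#' @param k_synaptic Synaptic time-constant multiplier for the spatial
#'   recipes (tau_bs = k * tau_bs0).
#' @return A validated configuration list (class `"ei_config"`) for
#'   [run_experiment()].
#' @export
recipe_config <- function(name = c("fig2a", "fig2b", "fig3", "fig5a",
                                   "fig5b", "fig5cd", "fig5ef", "fig6a",
                                   "fig6b"),
                          scale = 1, seed = 1L, period = NULL,
                          k_synaptic = 1) {
  name <- match.arg(name)
  if (scale <= 0 || scale > 1) stop("'scale' must lie in (0, 1]")
  cfg <- switch(name,
    fig2a = list(
      experiment = "uncoupled",
      drive = list(mu_F = 1, mu_step = 5, step_time = 5),
      simulation = list(n = max(2L, round(2500 * scale)), duration = 10,
                        dt = 0.002, noise = "constant_vmr", beta = 1,
                        theta = 1, tau = 1),
      analysis = list(bin = 0.1)),
    fig2b = list(
      experiment = "uncoupled",
      drive = list(mu_F = 1, mu_step = 5, step_time = 5),
      simulation = list(n = max(2L, round(2500 * scale)), duration = 10,
                        dt = 0.002, noise = "constant_sigma", sigma2 = 1,
                        theta = 1, tau = 1),
      analysis = list(bin = 0.1)),
    fig3 = list(
      experiment = "homogeneous",
      network = list(N = max(10L, round(1e4 * scale)), q_I = 0.2, p = 0.25,
                     j = list(EE = 0.25, EI = -1, IE = 0.4, II = -1),
                     f = list(E = 3, I = 2), theta = 15,
                     tau_m = list(E = 15, I = 10),
                     tau_s = list(E = 6, I = 5)),
      drive = list(mu_F = 0.1, amplitude = 0.05, period = 50,
                   vmr_mode = "poisson_like", beta_F = 0.1),
      simulation = list(duration = 150, dt = 0.05),
      analysis = list(bin = 0.5)),
    fig5a = spatial_recipe(scale, k_synaptic, stimulus = list(
      center = c(0.25, 0.5), radius = 0.05, magnitude = 1.5,
      magnitude_step = 15, step_time = 75, trajectory = "static",
      background_mean = 0.5, background_sd = 0.25),
      duration = 150),
    fig5b = spatial_recipe(scale, k_synaptic, stimulus = list(
      center = c(0.25, 0.5), radius = 0.05,
      sinusoid = list(A = 30, B = 1.5, C = 30, T = period %||% 50),
      trajectory = "static",
      background_mean = 0.5, background_sd = 0.25),
      duration = 4 * (period %||% 50)),
    fig5cd = spatial_recipe(scale, k_synaptic, stimulus = list(
      center = c(0.1, 0.5), radius = 0.05, magnitude = 10,
      trajectory = "linear", velocity = c(0.002, 0)),
      duration = 400, window = 10, n_trials = 5),
    fig5ef = spatial_recipe(scale, k_synaptic, stimulus = list(
      center = c(0.5, 0.5), radius = 0.05, magnitude = 10,
      trajectory = "circular", orbit_radius = 0.2,
      period = period %||% 400),
      duration = period %||% 400, window = 10, n_trials = 5),
    fig6a = spatial_recipe(scale, k_synaptic, stimulus = list(
      center = c(0.25, 0.5), radius = 0.05,
      sinusoid = list(A = 30, B = 1.5, C = 30, T = period %||% 50),
      trajectory = "static"),
      duration = 5 * (period %||% 50)),
    fig6b = spatial_recipe(scale, k_synaptic, stimulus = list(
      center = c(0.5, 0.5), radius = 0.05, magnitude = 10,
      trajectory = "circular", orbit_radius = 0.2,
      period = period %||% 400),
      duration = period %||% 400, window = 10, n_trials = 5))
  cfg$seed <- as.integer(seed)
  cfg$scale <- scale
  validate_config(cfg)
}

# shared spatial preset: 50x50 pixel layer, 80x80 E, 40x40 I grids and the
# local-connectivity parameter set, scaled per axis by sqrt(scale)
spatial_recipe <- function(scale, k_synaptic, stimulus, duration,
                           window = 2, n_trials = 1) {
  ax <- sqrt(scale)
  list(
    experiment = "spatial",
    spatial = list(
      nE = max(4L, round(80 * ax)), nI = max(2L, round(40 * ax)),
      nF = max(2L, round(50 * ax)),
      p = list(EE = 0.02, EI = 0.08, IE = 0.06, II = 0.08,
               EF = 0.05, IF = 0.025),
      j = list(EE = 80, EI = -320, IE = 40, II = -320,
               EF = 140, IF = 93.3),
      A = list(E = 0.02, I = 0.02, F = 0.05),
      theta = 15, tau_m = list(E = 15, I = 10),
      tau_s = list(E = 5, I = 2.5, F = 5), tau_F = 1, theta_F = 15),
    stimulus = stimulus,
    simulation = list(duration = duration, k_synaptic = k_synaptic),
    analysis = list(window = window, bin = 2, n_trials = n_trials))
}

# ---- configuration -> model objects --------------------------------------

config_to_network <- function(cfg) {
  nw <- cfg$network
  if (is.null(nw)) stop("configuration lacks a 'network' block")
  balanced_network(
    N = nw$N, q_I = nw$q_I %||% 0.2,
    p = block_to_matrix(nw$p, POPS, POPS, "p"),
    j = block_to_matrix(nw$j, POPS, POPS, "j"),
    f = unlist(nw$f), theta = nw$theta, v0 = nw$v0 %||% 0,
    tau_m = unlist(nw$tau_m), tau_s = unlist(nw$tau_s),
    reflecting_barrier = isTRUE(nw$reflecting_barrier))
}

config_to_spatial_network <- function(cfg) {
  sp <- cfg$spatial
  if (is.null(sp)) stop("configuration lacks a 'spatial' block")
  k <- cfg$simulation$k_synaptic %||% 1
  spatial_network(
    nE = sp$nE, nI = sp$nI, nF = sp$nF,
    p = block_to_matrix(sp$p, POPS, SPAT_PRE, "p"),
    j = block_to_matrix(sp$j, POPS, SPAT_PRE, "j"),
    A = unlist(sp$A),
    theta = sp$theta %||% 15, tau_m = unlist(sp$tau_m),
    tau_s = unlist(sp$tau_s) * k,
    tau_F = sp$tau_F %||% 1, theta_F = sp$theta_F %||% 15,
    reflecting_barrier = !isFALSE(sp$reflecting_barrier),
    torus = !isFALSE(sp$torus))
}

config_to_drive <- function(cfg) {
  d <- cfg$drive
  if (is.null(d)) stop("configuration lacks a 'drive' block")
  feedforward_drive(make_mu_fun(d),
                    vmr_mode = d$vmr_mode %||% "poisson_like",
                    beta_F = d$beta_F %||% 0.1, sigma2_F = d$sigma2_F)
}

config_to_stimulus <- function(cfg) {
  st <- cfg$stimulus
  if (is.null(st)) stop("configuration lacks a 'stimulus' block")
  magnitude <- if (!is.null(st$sinusoid)) {
    sn <- st$sinusoid
    sinusoid_magnitude(sn$A, sn$B, sn$C, sn$T)
  } else if (!is.null(st$magnitude_step)) {
    m0 <- st$magnitude; m1 <- st$magnitude_step; ts <- st$step_time
    function(t) if (t < ts) m0 else m1
  } else st$magnitude
  disc_stimulus(center = unlist(st$center), radius = st$radius,
                magnitude = magnitude,
                trajectory = st$trajectory %||% "static",
                velocity = unlist(st$velocity %||% c(0, 0)),
                orbit_radius = st$orbit_radius %||% 0.2,
                period = st$period %||% 100, phase = st$phase %||% 0,
                background_mean = st$background_mean %||% 0,
                background_sd = st$background_sd %||% 0)
}

# scalar time course of the drive block: optional step and/or sinusoid
make_mu_fun <- function(d) {
  base <- d$mu_F
  if (is.null(base)) stop("drive block needs 'mu_F'")
  step_t <- d$step_time; step_v <- d$mu_step
  amp <- d$amplitude; per <- d$period
  function(t) {
    m <- if (!is.null(step_t) && t >= step_t) step_v else base
    if (!is.null(amp)) m <- m + amp * sin(2 * pi * t / per)
    m
  }
}

# time-averaged drive mean (used for stationary-rate predictions)
mean_mu_F <- function(d) d$mu_F %||% 0

# named list (EE, EI, ... keys) or scalar -> (post, pre) matrix
block_to_matrix <- function(x, post, pre, what) {
  if (is.null(x)) stop(sprintf("missing '%s' block", what))
  if (is.matrix(x) || length(x) == 1L) return(x)
  m <- matrix(NA_real_, length(post), length(pre),
              dimnames = list(post = post, pre = pre))
  for (a in post) for (b in pre) {
    key <- paste0(a, b)
    if (is.null(x[[key]]))
      stop(sprintf("'%s' block lacks entry '%s'", what, key))
    m[a, b] <- x[[key]]
  }
  m
}
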