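#' Regular square layout of neuron positions
#'
#' Places `nx * ny` units at cell centers of a regular grid on the unit
#' square, the arrangement used for every layer of the spatial network
#' (pixels, excitatory and inhibitory neurons).
#'
#' @param nx,ny Grid dimensions (`ny` defaults to `nx`).
#' @return A data.frame with columns `x`, `y` (column-major over the grid,
#'   x varying fastest) and attributes `nx`, `ny`; class
#'   `"spatial_layout"`.
#' @export
spatial_layout <- function(nx, ny = nx) {
  xs <- (seq_len(nx) - 0.5) / nx
  ys <- (seq_len(ny) - 0.5) / ny
  out <- data.frame(x = rep(xs, times = ny), y = rep(ys, each = nx))
  attr(out, "nx") <- nx
  attr(out, "ny") <- ny
  class(out) <- c("spatial_layout", "data.frame")
  out
}

# squared pairwise distance, optionally wrapped on the unit torus
dist2_xy <- function(x1, y1, x2, y2, torus = TRUE) {
  dx <- abs(outer(x1, x2, "-"))
  dy <- abs(outer(y1, y2, "-"))
  if (torus) {
    dx <- pmin(dx, 1 - dx)
    dy <- pmin(dy, 1 - dy)
  }
  dx^2 + dy^2
}

#' Disc stimulus specification
#'
#' A disc-shaped luminance stimulus on the unit square: intensity
#' `magnitude(t)` inside the disc, 0 outside, plus optional i.i.d. Gaussian
#' background noise (clipped at 0).  The disc center can be static, move on
#' a straight line at constant velocity, or move counterclockwise on a
#' circle at constant angular speed.
#'
#' @param center Disc center `c(x, y)` at `t = 0` (static mode) or the
#'   trajectory's start/center.
#' @param radius Disc radius (> 0).
#' @param magnitude Intensity: scalar, or function of time (e.g. a step or
#'   the sinusoid \eqn{\mu(t) = A \sin(B \cdot 2\pi t / T) + C}).
#' @param trajectory `"static"`, `"linear"` or `"circular"`.
#' @param velocity Velocity `c(vx, vy)` for linear motion.
#' @param orbit_radius,period,phase Circle radius, revolution period and
#'   initial phase for circular (counterclockwise) motion around `center`.
#' @param background_mean,background_sd Background noise intensity added to
#'   every pixel each step (Gaussian, clipped at 0).
#' @return An object of class `"stimulus_spec"`.
#' @export
disc_stimulus <- function(center = c(0.25, 0.5), radius = 0.05, magnitude = 15,
                          trajectory = c("static", "linear", "circular"),
                          velocity = c(0, 0), orbit_radius = 0.2,
                          period = 100, phase = 0,
                          background_mean = 0, background_sd = 0) {
  trajectory <- match.arg(trajectory)
  if (radius <= 0) stop("'radius' must be positive")
  if (background_mean < 0 || background_sd < 0)
    stop("background noise parameters must be non-negative")
  structure(list(center = center, radius = radius,
                 magnitude = if (is.function(magnitude)) magnitude
                             else function(t) magnitude,
                 trajectory = trajectory, velocity = velocity,
                 orbit_radius = orbit_radius, period = period, phase = phase,
                 background_mean = background_mean,
                 background_sd = background_sd),
            class = "stimulus_spec")
}

#' Sinusoidal magnitude function
#'
#' Convenience constructor for the intensity profile
#' \eqn{\mu(t) = A \sin(B \cdot 2\pi t / T) + C}, clipped at 0.
#'
#' @param A,B,C,T Amplitude, frequency multiplier, offset and period.
#' @return Function of time.
#' @export
sinusoid_magnitude <- function(A = 30, B = 3 / 2, C = 30, T = 50) {
  force(A); force(B); force(C); force(T)
  function(t) pmax(A * sin(B * 2 * pi * t / T) + C, 0)
}

#' Disc center position at time t
#'
#' @param spec A [disc_stimulus()].
#' @param t Time (vectorized).
#' @param torus Wrap the position onto the unit torus.
#' @return Matrix with columns `x`, `y`.
#' @export
trajectory_position <- function(spec, t, torus = TRUE) {
  pos <- switch(spec$trajectory,
    static = cbind(x = rep(spec$center[1], length(t)),
                   y = rep(spec$center[2], length(t))),
    linear = cbind(x = spec$center[1] + spec$velocity[1] * t,
                   y = spec$center[2] + spec$velocity[2] * t),
    circular = {
      ang <- spec$phase + 2 * pi * t / spec$period  # counterclockwise
      cbind(x = spec$center[1] + spec$orbit_radius * cos(ang),
            y = spec$center[2] + spec$orbit_radius * sin(ang))
    })
  if (torus) pos <- pos %% 1
  pos
}

#' Render a stimulus onto a pixel grid
#'
#' Pixels whose centers lie strictly within the disc receive the stimulus
#' magnitude; all others 0.  Background noise (if configured) is then added
#' to every pixel and the field clipped at 0.  Distances to the disc
#' center are wrapped when `torus = TRUE`.
#'
#' @param spec A [disc_stimulus()].
#' @param t Time.
#' @param layout A [spatial_layout()] of pixel centers.
#' @param noise Draw the background noise (uses the current RNG state);
#'   set `FALSE` for the noiseless field.
#' @param torus Wrapped distance to the disc center.
#' @return Numeric intensity vector over the layout's pixels.
#' @export
render_stimulus <- function(spec, t, layout, noise = TRUE, torus = TRUE) {
  pos <- trajectory_position(spec, t, torus = torus)
  dx <- abs(layout$x - pos[1, "x"])
  dy <- abs(layout$y - pos[1, "y"])
  if (torus) {
    dx <- pmin(dx, 1 - dx)
    dy <- pmin(dy, 1 - dy)
  }
  field <- ifelse(dx^2 + dy^2 < spec$radius^2, spec$magnitude(t), 0)
  if (noise && (spec$background_mean > 0 || spec$background_sd > 0)) {
    field <- field + pmax(stats::rnorm(nrow(layout), spec$background_mean,
                                       spec$background_sd), 0)
  }
  pmax(field, 0)
}

#' Encode an intensity field sequence into pixel spikes
#'
#' The synthetic event-camera layer: one non-leaky integrate-and-fire
#' neuron per pixel integrates its luminance intensity
#' (\eqn{\tau_F\,dv/dt = I(t)}) and fires on reaching `theta`, so the
#' steady-state spike rate of a pixel equals `intensity / (theta * tau_F)`.
#'
#' @param field Intensity source: a function `field(t)` returning the
#'   intensity vector over the layout, or a constant vector.
#' @param layout A [spatial_layout()] of pixel centers.
#' @param duration,dt Encoding span and step.
#' @param tau_F,theta Pixel membrane constant (small, reflecting the high
#'   sampling rate) and threshold.
#' @param seed Optional seed (initial pixel phases and any field noise).
#' @param init `"uniform"` staggers initial potentials on `[0, theta)`;
#'   `"reset"` starts all pixels at 0 (synchronous).
#' @return An `"uncoupled_sim"`-like object with pixel spike `events`
#'   (population `"F"`), per-step `counts`, and per-pixel total counts
#'   `pixel_counts`.
#' @export
spike_camera_encode <- function(field, layout, duration, dt = 0.05,
                                tau_F = 1, theta = 15, seed = NULL,
                                init = c("uniform", "reset")) {
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(layout)
  field_fun <- if (is.function(field)) field else function(t) field
  v <- if (init == "uniform") stats::runif(n, 0, theta) else numeric(n)
  nsteps <- max(1L, round(duration / dt))
  ev <- vector("list", nsteps)
  counts <- integer(nsteps)
  pixel_counts <- integer(n)
  for (s in seq_len(nsteps)) {
    I <- field_fun((s - 1L) * dt)
    v <- v + I * dt / tau_F
    fired <- v >= theta
    nf <- sum(fired)
    counts[s] <- nf
    if (nf) {
      idx <- which(fired)
      ev[[s]] <- idx
      pixel_counts[idx] <- pixel_counts[idx] + 1L
      v[fired] <- 0
    }
  }
  events <- collect_events(list(F = ev), dt)
  structure(list(events = events, counts = counts, pixel_counts = pixel_counts,
                 n = n, dt = dt, duration = nsteps * dt,
                 theta = theta, tau = tau_F, layout = layout),
            class = "uncoupled_sim")
}
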