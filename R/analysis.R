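#' Population firing-rate trace from a spike table
#'
#' Bins spikes and divides by (number of neurons x bin width), optionally
#' restricting to a spatial region (the standard readout for comparing the
#' balanced layer's response with the stimulus at a location of interest).
#'
#' @param events Spike data.frame with columns `population`, `neuron`,
#'   `time` (as produced by the simulators).
#' @param n_neurons Number of neurons the rate is normalized by (the
#'   region's count when a region is given).
#' @param bin Bin width (> 0).
#' @param population Restrict to one population label (`NULL` = all).
#' @param positions Optional layout (data.frame `x`, `y`) indexed by
#'   `neuron`, required with `region`.
#' @param region Optional logical mask over neurons, or a function of
#'   `(x, y)` returning one (e.g. the stimulated disc area).
#' @param t_range Time span `c(from, to)` covered by the trace; default
#'   `c(0, max(time))`.
#' @return data.frame of class `"rate_trace"`: bin centers `t` and rate
#'   `r` in spikes per neuron per time unit.
#' @export
population_rate <- function(events, n_neurons, bin = 0.5, population = NULL,
                            positions = NULL, region = NULL, t_range = NULL) {
  if (bin <= 0) stop("'bin' must be positive")
  if (!is.null(population))
    events <- events[events$population == population, , drop = FALSE]
  if (!is.null(region)) {
    if (is.null(positions))
      stop("'positions' are required to evaluate a spatial region mask")
    mask <- if (is.function(region)) region(positions$x, positions$y) else region
    if (!any(mask)) stop("empty region: the mask selects no neurons")
    n_neurons <- sum(mask)
    events <- events[mask[events$neuron], , drop = FALSE]
  }
  if (is.null(t_range))
    t_range <- c(0, if (nrow(events)) max(events$time) else bin)
  breaks <- seq(t_range[1], t_range[2] + bin - 1e-9, by = bin)
  cnt <- if (nrow(events))
    tabulate(findInterval(events$time, breaks, left.open = TRUE,
                          rightmost.closed = FALSE),
             nbins = length(breaks) - 1L)
  else integer(length(breaks) - 1L)
  out <- data.frame(t = breaks[-length(breaks)] + bin / 2,
                    r = cnt / (n_neurons * bin))
  class(out) <- c("rate_trace", "data.frame")
  out
}

# wrap angles into (-pi, pi]
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

# weighted centroid of positions, circular (torus-aware) per coordinate
torus_centroid <- function(x, y, w, torus = TRUE) {
  if (!torus) return(c(x = sum(w * x) / sum(w), y = sum(w * y) / sum(w)))
  cx <- (atan2(sum(w * sin(2 * pi * x)), sum(w * cos(2 * pi * x))) / (2 * pi)) %% 1
  cy <- (atan2(sum(w * sin(2 * pi * y)), sum(w * cos(2 * pi * y))) / (2 * pi)) %% 1
  c(x = cx, y = cy)
}

#' Decode an object location as an activity centroid
#'
#' Intensity-weighted centroid of above-threshold activity; the threshold
#' is a configurable multiple of the spatial median (of the nonzero mean
#' when the median is zero, as in sparse spiking regimes).  On the torus
#' the centroid is the circular mean per coordinate.
#'
#' @param values Activity per unit (rates or spike counts).
#' @param positions Layout data.frame with `x`, `y`.
#' @param threshold_factor Multiple of the spatial median defining the
#'   background threshold (default 2).
#' @param torus Use circular means.
#' @return Named vector `c(x, y)`, or `c(NA, NA)` when no unit is above
#'   threshold ("no object detected").
#' @export
decode_centroid <- function(values, positions, threshold_factor = 2,
                            torus = TRUE) {
  med <- stats::median(values)
  thr <- if (med > 0) threshold_factor * med else 0
  keep <- values > thr
  if (!any(keep)) return(c(x = NA_real_, y = NA_real_))
  w <- values[keep] - thr
  torus_centroid(positions$x[keep], positions$y[keep], w, torus = torus)
}

#' Decode an object trajectory from windowed spikes
#'
#' Splits the spike table into time windows and applies
#' [decode_centroid()] to the per-neuron spike counts of each window.
#'
#' @param events Spike data.frame (`population`, `neuron`, `time`).
#' @param positions Layout of the decoded population.
#' @param window Window length.
#' @param population Population label to decode.
#' @param t_range Span to decode; default the events' span.
#' @param threshold_factor,torus Passed to [decode_centroid()].
#' @return data.frame with window centers `t`, decoded `x`, `y` and the
#'   spike count `n` per window (`x`, `y` are `NA` for empty windows).
#' @export
decode_positions <- function(events, positions, window = 2, population = "E",
                             t_range = NULL, threshold_factor = 2,
                             torus = TRUE) {
  ev <- events[events$population == population, , drop = FALSE]
  if (is.null(t_range)) t_range <- c(0, if (nrow(ev)) max(ev$time) else window)
  starts <- seq(t_range[1], t_range[2] - window + 1e-9, by = window)
  out <- data.frame(t = starts + window / 2, x = NA_real_, y = NA_real_,
                    n = 0L)
  for (k in seq_along(starts)) {
    sel <- ev$time > starts[k] & ev$time <= starts[k] + window
    if (!any(sel)) next
    cnt <- tabulate(ev$neuron[sel], nbins = nrow(positions))
    out$n[k] <- sum(cnt)
    xy <- decode_centroid(cnt, positions, threshold_factor, torus)
    out$x[k] <- xy[["x"]]; out$y[k] <- xy[["y"]]
  }
  out
}

#' Temporal phase lag between two rate traces
#'
#' Estimates the phase of each trace at the stimulus frequency `1/T` from
#' the single-frequency Fourier coefficient over an integer number of
#' periods (equivalent to least-squares sinusoid regression) and returns
#' the wrapped difference.  Positive lag means the response lags the
#' reference.
#'
#' @param reference,response Rate traces (data.frames with `t`, `r`) on a
#'   common uniform time grid.
#' @param T Stimulus period.
#' @param discard Initial transient to drop (default one period).
#' @return List of class `"phase_lag"`: `phase` (radians in (-pi, pi]),
#'   per-trace amplitudes, and `reliable` (`FALSE` when either amplitude
#'   is below twice its off-frequency noise floor).
#' @export
temporal_phase_lag <- function(reference, response, T, discard = T) {
  if (nrow(reference) != nrow(response) ||
      max(abs(reference$t - response$t)) > 1e-8)
    stop("traces must share the same uniform time grid")
  keep <- reference$t > discard
  t <- reference$t[keep]
  span <- diff(range(t))
  if (span < 3 * T)
    stop("period not resolvable: traces must cover at least 3 periods after the transient")
  n_per <- floor(span / T)
  keep2 <- t <= t[1] + n_per * T
  t <- t[keep2]
  comp <- function(r) {
    r <- r[keep][keep2]
    c0 <- sum((r - mean(r)) * exp(-1i * 2 * pi * t / T))
    noise <- stats::mad(diff(r)) / sqrt(2) * sqrt(length(t)) + 1e-300
    list(phase = Arg(c0), amp = 2 * Mod(c0) / length(t), snr = Mod(c0) / noise)
  }
  a <- comp(reference$r); b <- comp(response$r)
  structure(list(phase = wrap_angle(a$phase - b$phase),
                 amp_reference = a$amp, amp_response = b$amp,
                 reliable = a$snr > 2 && b$snr > 2, T = T),
            class = "phase_lag")
}

#' @export
print.phase_lag <- function(x, ...) {
  cat(sprintf("phase lag %.4g rad (T = %g)%s\n", x$phase, x$T,
              if (!x$reliable) "  [unreliable: amplitude near noise floor]" else ""))
  invisible(x)
}

#' Spatial phase lag of a decoded circular trajectory
#'
#' Converts the decoded positions and the reference circular motion to
#' angle-vs-time about the motion circle's center and returns the circular
#' mean of (reference angle - decoded angle), weighted by the per-window
#' spike counts.  Positive lag means the decoded position trails the
#' stimulus.
#'
#' @param decoded Output of [decode_positions()].
#' @param spec The circular-motion [disc_stimulus()] driving the run.
#' @param discard Initial transient to drop (default one revolution).
#' @return A `"phase_lag"` list (`phase` in radians, `n` windows used).
#' @export
spatial_phase_lag <- function(decoded, spec, discard = spec$period) {
  if (spec$trajectory != "circular")
    stop("spatial phase lag is defined for circular-motion stimuli")
  d <- decoded[decoded$t > discard & !is.na(decoded$x), , drop = FALSE]
  if (!nrow(d)) stop("no decoded positions after the transient")
  dx <- wrap_unit(d$x - spec$center[1])
  dy <- wrap_unit(d$y - spec$center[2])
  radii <- sqrt(dx^2 + dy^2)
  if (mean(radii) < spec$orbit_radius / 2)
    stop("tracking lost: decoded radius below half the reference orbit radius")
  dec_ang <- atan2(dy, dx)
  ref_ang <- spec$phase + 2 * pi * d$t / spec$period
  diffs <- wrap_angle(ref_ang - dec_ang)
  w <- pmax(d$n, 1)
  phase <- atan2(sum(w * sin(diffs)), sum(w * cos(diffs)))
  structure(list(phase = phase, T = spec$period, n = nrow(d),
                 reliable = TRUE),
            class = "phase_lag")
}

# signed displacement on the unit torus, in (-0.5, 0.5]
wrap_unit <- function(d) {
  d <- (d + 0.5) %% 1 - 0.5
  d
}

# circular mean of unit-interval coordinates (NAs dropped; NA if all NA)
circular_mean_unit <- function(z) {
  z <- z[!is.na(z)]
  if (!length(z)) return(NA_real_)
  (atan2(mean(sin(2 * pi * z)), mean(cos(2 * pi * z))) / (2 * pi)) %% 1
}

#' Trial-averaged object tracking through the full pipeline
#'
#' Runs `n_trials` independent simulations of a spatial network under the
#' same moving stimulus (each trial draws a fresh connectivity
#' realization and noise stream), decodes the object position per time
#' window from the balanced excitatory layer and from the pixel layer
#' with [decode_positions()], averages the decoded positions across
#' trials (circular mean per coordinate on the torus), and reports the
#' root-mean-square torus distance between the two averaged tracks after
#' an initial transient.  Averaging across connectivity realizations is
#' essential at small grid sizes: a single realization's frozen in-degree
#' fluctuations displace the activity bump by a position-dependent offset
#' that no amount of temporal averaging removes.
#'
#' @param net A [spatial_network()].
#' @param stimulus A moving [disc_stimulus()].
#' @param duration Simulated span per trial.
#' @param n_trials Number of independent trials averaged.
#' @param window Decode window length.
#' @param seed Optional seed (one stream across all trials).
#' @param discard Initial span excluded from the error summary (default
#'   one tenth of `duration`).
#' @param dt Integration step (default the simulator's).
#' @return An object of class `"object_tracking"`: data.frame `track`
#'   with window centers `t`, averaged decodes `xE, yE, xF, yF` and the
#'   reference trajectory `x_ref, y_ref`; scalars `rmse` (E vs F decode,
#'   the tracking figure of merit), `rmse_E_ref` and `rmse_F_ref` (each
#'   decode against the reference trajectory), plus the settings.
#' @export
track_object <- function(net, stimulus, duration, n_trials = 5, window = 10,
                         seed = NULL, discard = duration / 10, dt = NULL) {
  if (!inherits(net, "spatial_network"))
    stop("'net' must be a spatial_network")
  if (!is.null(seed)) set.seed(seed)
  dE <- vector("list", n_trials); dF <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    sim <- simulate(net, stimulus = stimulus, duration = duration, dt = dt,
                    warn_unbalanced = FALSE)
    dF[[k]] <- decode_positions(sim$events, net$layouts$F, window, "F",
                                t_range = c(0, duration), torus = net$torus)
    dE[[k]] <- decode_positions(sim$events, net$layouts$E, window, "E",
                                t_range = c(0, duration), torus = net$torus)
  }
  t_win <- dE[[1]]$t
  avg <- function(decs, col) vapply(seq_along(t_win), function(i)
    circular_mean_unit(vapply(decs, function(d) d[[col]][i], numeric(1))),
    numeric(1))
  track <- data.frame(t = t_win,
                      xE = avg(dE, "x"), yE = avg(dE, "y"),
                      xF = avg(dF, "x"), yF = avg(dF, "y"))
  ref <- trajectory_position(stimulus, t_win, torus = net$torus)
  track$x_ref <- ref[, "x"]; track$y_ref <- ref[, "y"]
  ok <- track$t > discard & !is.na(track$xE) & !is.na(track$xF)
  rms <- function(dx, dy) sqrt(mean(dx^2 + dy^2))
  structure(list(
    track = track,
    rmse = if (any(ok)) rms(wrap_unit(track$xE[ok] - track$xF[ok]),
                            wrap_unit(track$yE[ok] - track$yF[ok]))
           else NA_real_,
    rmse_E_ref = if (any(ok)) rms(wrap_unit(track$xE[ok] - track$x_ref[ok]),
                                  wrap_unit(track$yE[ok] - track$y_ref[ok]))
                 else NA_real_,
    rmse_F_ref = if (any(ok)) rms(wrap_unit(track$xF[ok] - track$x_ref[ok]),
                                  wrap_unit(track$yF[ok] - track$y_ref[ok]))
                 else NA_real_,
    n_windows = sum(ok), n_trials = n_trials, window = window,
    discard = discard),
    class = "object_tracking")
}

#' @export
print.object_tracking <- function(x, ...) {
  cat(sprintf(paste0(
    "<object_tracking> %d trials, %d windows (length %g)\n",
    "  RMSE balanced-layer vs pixel-layer decode: %.4g\n",
    "  RMSE vs reference trajectory: E %.4g, pixels %.4g\n"),
    x$n_trials, x$n_windows, x$window,
    x$rmse, x$rmse_E_ref, x$rmse_F_ref))
  invisible(x)
}

#' Asynchrony diagnostics: pairwise correlations and Fano factors
#'
#' Bins each neuron's spike train and reports the mean Pearson correlation
#' of spike counts over randomly sampled neuron pairs (with its standard
#' error) plus per-neuron Fano factors.  Near-zero mean correlation is the
#' hallmark of the asynchronous balanced state.
#'
#' @param events Spike data.frame.
#' @param n_neurons Number of neurons in the population.
#' @param bin Count window length.
#' @param population Population label (`NULL` = all rows).
#' @param n_pairs Number of sampled pairs.
#' @param t_range Analysis span; default the events' span.
#' @param seed Optional seed for the pair sampling.
#' @return List: `mean_correlation`, `se`, `correlations`, `fano`
#'   (per active neuron), `n_excluded` (zero-variance neurons dropped).
#' @export
asynchrony_diagnostics <- function(events, n_neurons, bin = 1,
                                   population = NULL, n_pairs = 1000,
                                   t_range = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(population))
    events <- events[events$population == population, , drop = FALSE]
  if (is.null(t_range)) t_range <- c(0, max(events$time))
  nb <- floor(diff(t_range) / bin)
  if (nb < 2) stop("need at least 2 count bins")
  sel <- events$time > t_range[1] & events$time <= t_range[1] + nb * bin
  bin_idx <- ceiling((events$time[sel] - t_range[1]) / bin)
  M <- as.matrix(Matrix::sparseMatrix(i = events$neuron[sel], j = bin_idx,
                                      x = 1, dims = c(n_neurons, nb)))
  vars <- apply(M, 1L, stats::var)
  means <- rowMeans(M)
  active <- which(vars > 0)
  if (length(active) < 2)
    stop("need at least 2 neurons with variable spike counts")
  fano <- vars[active] / means[active]
  pairs <- matrix(c(sample(active, n_pairs, replace = TRUE),
                    sample(active, n_pairs, replace = TRUE)), ncol = 2)
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  cors <- vapply(seq_len(nrow(pairs)), function(k)
    stats::cor(M[pairs[k, 1], ], M[pairs[k, 2], ]), numeric(1))
  list(mean_correlation = mean(cors),
       se = stats::sd(cors) / sqrt(length(cors)),
       correlations = cors,
       fano = fano,
       n_excluded = n_neurons - length(active))
}
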