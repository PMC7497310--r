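#' Write / read spike event tables
#'
#' Events are stored as plain tab-delimited text with a one-line header
#' (`population  neuron  time`), times at full (17 significant digit)
#' precision, plus an optional JSON sidecar (`<path>.json`) carrying
#' metadata such as seeds and parameters.
#'
#' @param events Spike data.frame (`population`, `neuron`, `time`).
#' @param path Output file.
#' @param metadata Optional list written to the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_spike_events <- function(events, path, metadata = NULL) {
  df <- events
  df$time <- formatC(df$time, digits = 17, format = "g")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata))
    jsonlite::write_json(metadata, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' @rdname write_spike_events
#' @export
read_spike_events <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "numeric"))
  df
}

#' Write / read numeric trace tables (rates, densities, maps)
#'
#' Tab-delimited text with header, numbers at 17 significant digits so the
#' round trip is lossless at double precision.
#'
#' @param df Data frame of numeric columns.
#' @param path File path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_trace <- function(df, path) {
  out <- as.data.frame(lapply(df, function(col)
    if (is.numeric(col)) formatC(col, digits = 17, format = "g") else col))
  names(out) <- names(df)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML or JSON configuration (by file extension) and validates it
#' against the experiment schema: unknown keys are rejected with an error
#' naming the key, defaults are filled from the matching canned recipe
#' when `recipe` is set.
#'
#' @param path Configuration file (`.yaml`, `.yml` or `.json`).
#' @return A validated configuration list of class `"ei_config"`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported configuration format (use .yaml or .json): ", path)
  if (!is.null(cfg$recipe)) {
    base <- recipe_config(cfg$recipe,
                          scale = if (is.null(cfg$scale)) 1 else cfg$scale,
                          seed = if (is.null(cfg$seed)) 1L else cfg$seed)
    cfg <- utils::modifyList(base, cfg[setdiff(names(cfg), "recipe")])
  }
  validate_config(cfg)
}

CONFIG_SCHEMA <- list(
  top = c("experiment", "seed", "scale", "network", "spatial", "drive",
          "stimulus", "simulation", "analysis", "recipe"),
  network = c("N", "q_I", "p", "j", "f", "theta", "v0", "tau_m", "tau_s",
              "reflecting_barrier"),
  spatial = c("nE", "nI", "nF", "p", "j", "A", "theta", "tau_m", "tau_s",
              "tau_F", "theta_F", "reflecting_barrier", "torus"),
  drive = c("mu_F", "mu_step", "step_time", "amplitude", "period",
            "vmr_mode", "beta_F", "sigma2_F", "mu0"),
  stimulus = c("center", "radius", "magnitude", "magnitude_step",
               "step_time", "sinusoid", "trajectory", "velocity",
               "orbit_radius", "period", "phase", "background_mean",
               "background_sd"),
  simulation = c("duration", "dt", "n", "mu", "beta", "sigma2", "noise",
                 "theta", "tau", "k_synaptic"),
  analysis = c("bin", "window", "threshold_factor", "discard",
               "region_radius", "n_trials"))

validate_config <- function(cfg) {
  check_keys <- function(block, allowed, where) {
    extra <- setdiff(names(block), allowed)
    if (length(extra))
      stop(sprintf("unknown configuration key '%s' in %s", extra[1], where))
  }
  check_keys(cfg, CONFIG_SCHEMA$top, "top level")
  for (blk in intersect(names(cfg), c("network", "spatial", "drive",
                                      "stimulus", "simulation", "analysis")))
    check_keys(cfg[[blk]], CONFIG_SCHEMA[[blk]], blk)
  if (is.null(cfg$experiment))
    stop("configuration must name an 'experiment' (uncoupled, homogeneous, spatial)")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "ei_config")
}

#' Run a configured experiment and write its artifacts
#'
#' Orchestrates the appropriate modules for the configured experiment
#' kind, writing the spike event table, rate traces, an analysis JSON and
#' a manifest (seed, package version, wall clock, event checksum) into
#' `out_dir`.  Re-running with the same configuration and seed reproduces
#' the event table bit for bit.
#'
#' @param cfg A configuration list from [load_config()] or
#'   [recipe_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest list, invisibly.
#' @export
run_experiment <- function(cfg, out_dir) {
  cfg <- validate_config(unclass(cfg))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  res <- switch(cfg$experiment,
    uncoupled = run_uncoupled_experiment(cfg),
    homogeneous = run_homogeneous_experiment(cfg),
    spatial = run_spatial_experiment(cfg),
    stop("unknown experiment kind: ", cfg$experiment))
  ev_path <- file.path(out_dir, "events.tsv")
  write_spike_events(res$events, ev_path, metadata = list(seed = cfg$seed))
  write_trace(res$rate, file.path(out_dir, "rates.tsv"))
  jsonlite::write_json(res$analysis, file.path(out_dir, "analysis.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    experiment = cfg$experiment, seed = cfg$seed,
    package_version = as.character(utils::packageVersion("einet")),
    wall_clock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    events_md5 = unname(tools::md5sum(ev_path)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

run_uncoupled_experiment <- function(cfg) {
  s <- cfg$simulation
  mu_fun <- make_mu_fun(cfg$drive)
  sim <- run_uncoupled(n = s$n, mu = mu_fun,
                       noise = if (is.null(s$noise)) "constant_vmr" else s$noise,
                       beta = if (is.null(s$beta)) 1 else s$beta,
                       sigma2 = if (is.null(s$sigma2)) 1 else s$sigma2,
                       theta = if (is.null(s$theta)) 1 else s$theta,
                       tau = if (is.null(s$tau)) 1 else s$tau,
                       duration = s$duration, dt = s$dt, seed = cfg$seed,
                       snapshot_times = s$duration)
  bin <- cfg$analysis$bin %||% 0.1
  tr <- rate_trace(sim, bin = bin)
  v <- sim$snapshots[[1]]$v
  ks <- ks_distance(v, function(q)
    fp_stationary_cdf(q, mu_fun(s$duration), (s$beta %||% 1) * mu_fun(s$duration),
                      s$theta %||% 1, s$tau %||% 1))
  list(events = sim$events, rate = tr,
       analysis = list(mean_rate = mean(sim$counts) / (sim$n * sim$dt),
                       ks_vs_stationary = ks))
}

run_homogeneous_experiment <- function(cfg) {
  net <- config_to_network(cfg)
  drv <- config_to_drive(cfg)
  s <- cfg$simulation
  sim <- simulate(net, seed = cfg$seed, drive = drv, duration = s$duration,
                  dt = s$dt)
  bin <- cfg$analysis$bin %||% 0.5
  tr <- rate_trace(sim, bin = bin)
  pred <- finite_N_rates(net, mean_mu_F(cfg$drive))
  list(events = sim$events, rate = tr,
       analysis = list(
         mean_rate_E = sum(sim$counts[, "E"]) / (sim$sizes[["E"]] * sim$duration),
         mean_rate_I = sum(sim$counts[, "I"]) / (sim$sizes[["I"]] * sim$duration),
         predicted_rate_E = unname(pred$r[["E"]]),
         predicted_rate_I = unname(pred$r[["I"]]),
         balance_ratios = as.list(check_balance_condition(net)$ratios)))
}

run_spatial_experiment <- function(cfg) {
  net <- config_to_spatial_network(cfg)
  stim <- config_to_stimulus(cfg)
  s <- cfg$simulation
  sim <- simulate(net, seed = cfg$seed, stimulus = stim,
                  duration = s$duration, dt = s$dt)
  window <- cfg$analysis$window %||% 2
  st <- cfg$stimulus
  moving <- !identical(st$trajectory %||% "static", "static")
  tracking <- NULL
  if (moving) {
    # trial-averaged decode: fresh connectivity per trial removes the
    # quenched single-realization decode bias
    tracking <- track_object(net, stim, duration = s$duration,
                             n_trials = cfg$analysis$n_trials %||% 1,
                             window = window, seed = cfg$seed, dt = s$dt,
                             discard = cfg$analysis$discard %||%
                               (s$duration / 10))
  } else {
    decF <- decode_positions(sim$events, net$layouts$F, window, "F",
                             t_range = c(0, sim$duration), torus = net$torus)
    decE <- decode_positions(sim$events, net$layouts$E, window, "E",
                             t_range = c(0, sim$duration), torus = net$torus)
  }
  rmse <- if (moving) tracking$rmse else {
    ok <- !is.na(decF$x) & !is.na(decE$x)
    if (any(ok)) sqrt(mean(wrap_unit(decE$x[ok] - decF$x[ok])^2 +
                             wrap_unit(decE$y[ok] - decF$y[ok])^2))
    else NA_real_
  }
  tr <- population_rate(sim$events, n_neurons = net$sizes[["E"]],
                        bin = cfg$analysis$bin %||% 2, population = "E",
                        t_range = c(0, sim$duration))
  analysis <- list(centroid_rmse_vs_camera = rmse,
                   spatial_balance = check_spatial_balance(net)[c("ratios", "balanced")])
  if (moving) {
    analysis$centroid_rmse_E_vs_reference <- tracking$rmse_E_ref
    analysis$centroid_rmse_camera_vs_reference <- tracking$rmse_F_ref
    analysis$tracking_trials <- tracking$n_trials
  }
  if (!is.null(st$sinusoid)) {
    # temporal phase lag between the pixel layer and the E layer at the
    # stimulated region
    bin <- cfg$analysis$bin %||% 2
    in_disc <- function(x, y) {
      dx <- pmin(abs(x - st$center[1]), 1 - abs(x - st$center[1]))
      dy <- pmin(abs(y - st$center[2]), 1 - abs(y - st$center[2]))
      dx^2 + dy^2 < (cfg$analysis$region_radius %||% (2 * st$radius))^2
    }
    trF <- population_rate(sim$events, n_neurons = 1L, bin = bin,
                           population = "F", positions = net$layouts$F,
                           region = in_disc, t_range = c(0, sim$duration))
    trE <- population_rate(sim$events, n_neurons = 1L, bin = bin,
                           population = "E", positions = net$layouts$E,
                           region = in_disc, t_range = c(0, sim$duration))
    pl <- tryCatch(temporal_phase_lag(trF, trE, T = st$sinusoid$T),
                   error = function(e) NULL)
    if (!is.null(pl))
      analysis$temporal_phase_lag <- pl[c("phase", "reliable", "T")]
  }
  if (identical(st$trajectory, "circular") && !is.null(tracking)) {
    dec_avg <- data.frame(t = tracking$track$t, x = tracking$track$xE,
                          y = tracking$track$yE, n = 1L)
    pl <- tryCatch(spatial_phase_lag(dec_avg, stim,
                                     discard = tracking$discard),
                   error = function(e) NULL)
    if (!is.null(pl))
      analysis$spatial_phase_lag <- pl[c("phase", "T", "n")]
  }
  list(events = sim$events, rate = tr, analysis = analysis)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Kolmogorov-Smirnov distance of a sample against a reference CDF
#'
#' Two-sided KS statistic `sup_v |F_n(v) - F(v)|` of the empirical
#' distribution of `x` against a target cumulative distribution function.
#'
#' @param x numeric sample.
#' @param cdf vectorized cumulative distribution function.
#' @return the KS distance (a scalar in `[0, 1]`).
#' @examples
#' ks_distance(runif(1000), function(q) pmin(pmax(q, 0), 1))
#' @export
ks_distance <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(abs(Fx - seq_len(n) / n), abs(Fx - (seq_len(n) - 1) / n))
}
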