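# Readout: population rates, centroid decoding, phase lags, asynchrony

poisson_events <- function(n_neurons, rate, duration, population = "E",
                           seed = 1) {
  set.seed(seed)
  k <- stats::rpois(n_neurons, rate * duration)
  data.frame(population = population,
             neuron = rep(seq_len(n_neurons), k),
             time = stats::runif(sum(k), 0, duration))
}

test_that("population_rate recovers a Poisson rate within sampling error", {
  ev <- poisson_events(50, 2, 20)
  tr <- population_rate(ev, 50, bin = 0.5, t_range = c(0, 20))
  se <- sqrt(2 / (50 * 20))
  expect_lt(abs(mean(tr$r) - 2), 3 * se)
  # halving the bin preserves the time-averaged rate exactly
  tr2 <- population_rate(ev, 50, bin = 0.25, t_range = c(0, 20))
  expect_equal(mean(tr2$r), mean(tr$r), tolerance = 1e-12)
})

test_that("region masks restrict the rate estimate and reject empty regions", {
  lay <- spatial_layout(10)
  ev <- poisson_events(100, 1, 10)
  # double the spikes of neurons in the left half
  left <- lay$x < 0.5
  extra <- ev[left[ev$neuron], ]
  tr_l <- population_rate(rbind(ev, extra), 100, bin = 1, positions = lay,
                          region = function(x, y) x < 0.5, t_range = c(0, 10))
  tr_r <- population_rate(rbind(ev, extra), 100, bin = 1, positions = lay,
                          region = function(x, y) x >= 0.5, t_range = c(0, 10))
  expect_gt(mean(tr_l$r), 1.5 * mean(tr_r$r))
  expect_error(population_rate(ev, 100, positions = lay,
                               region = function(x, y) x > 2), "empty region")
})

test_that("decode_centroid finds a dominant unit and rejects flat fields", {
  lay <- spatial_layout(10)
  vals <- rep(1, 100); vals[37] <- 10
  xy <- decode_centroid(vals, lay)
  expect_equal(unname(xy), c(lay$x[37], lay$y[37]))
  expect_true(all(is.na(decode_centroid(rep(3, 100), lay))))
})

test_that("centroid decoding wraps correctly across the torus seam", {
  lay <- spatial_layout(20)
  vals <- numeric(400)
  vals[lay$x %in% c(0.025, 0.975) & lay$y == 0.525] <- 5
  xy <- decode_centroid(vals, lay)
  expect_lt(min(xy[["x"]], 1 - xy[["x"]]), 1e-6)   # wraps to the seam, not 0.5
  expect_equal(unname(xy[["y"]]), 0.525, tolerance = 1e-9)
})

test_that("disc centroids are recovered to within half a pixel", {
  lay <- spatial_layout(50)
  worst <- 0
  for (cx in seq(0.2, 0.8, length.out = 5))
    for (cy in seq(0.18, 0.77, length.out = 5)) {
      spec <- disc_stimulus(center = c(cx, cy), radius = 0.08, magnitude = 5)
      f <- render_stimulus(spec, 0, lay, noise = FALSE)
      xy <- decode_centroid(f, lay)
      worst <- max(worst, abs(xy[["x"]] - cx), abs(xy[["y"]] - cy))
    }
  expect_lt(worst, 0.01)   # half of one 1/50 pixel
})

test_that("temporal phase lag recovers a known delay with the right sign", {
  T <- 20
  t <- seq(0.25, 5 * T, by = 0.25)
  ref <- data.frame(t = t, r = 2 + sin(2 * pi * t / T))
  lag <- data.frame(t = t, r = 2 + sin(2 * pi * (t - 5) / T))
  pl <- temporal_phase_lag(ref, lag, T)
  expect_equal(pl$phase, pi / 2, tolerance = 0.01)   # delay -> positive
  expect_true(pl$reliable)
  lead <- data.frame(t = t, r = 2 + sin(2 * pi * (t + 5) / T))
  expect_equal(temporal_phase_lag(ref, lead, T)$phase, -pi / 2,
               tolerance = 0.01)
})

test_that("phase lag flags noise-dominated traces and bad grids", {
  T <- 20
  t <- seq(0.25, 5 * T, by = 0.25)
  ref <- data.frame(t = t, r = 2 + sin(2 * pi * t / T))
  set.seed(3)
  noise <- data.frame(t = t, r = rnorm(length(t)))
  expect_false(temporal_phase_lag(ref, noise, T)$reliable)
  short <- ref[ref$t <= 3 * T, ]
  expect_error(temporal_phase_lag(short, short, T), "3 periods")
  shifted <- ref; shifted$t <- shifted$t + 0.1
  expect_error(temporal_phase_lag(ref, shifted, T), "time grid")
})

test_that("spatial phase lag recovers a known tracking delay", {
  spec <- disc_stimulus(center = c(0.5, 0.5), radius = 0.05,
                        trajectory = "circular", orbit_radius = 0.2,
                        period = 100)
  t <- seq(2, 300, by = 2)
  pos <- trajectory_position(spec, t - 5)
  dec <- data.frame(t = t, x = pos[, "x"], y = pos[, "y"], n = 1L)
  pl <- spatial_phase_lag(dec, spec)
  expect_equal(pl$phase, 2 * pi * 5 / 100, tolerance = 0.02 * 2 * pi * 5 / 100)
})

test_that("spatial phase lag rejects lost tracking and non-circular motion", {
  spec <- disc_stimulus(center = c(0.5, 0.5), radius = 0.05,
                        trajectory = "circular", orbit_radius = 0.2,
                        period = 100)
  t <- seq(2, 300, by = 2)
  dec0 <- data.frame(t = t, x = 0.5, y = 0.5, n = 1L)
  expect_error(spatial_phase_lag(dec0, spec), "tracking lost")
  static <- disc_stimulus(trajectory = "static")
  expect_error(spatial_phase_lag(dec0, static), "circular-motion")
  empty <- data.frame(t = t, x = NA_real_, y = NA_real_, n = 0L)
  expect_error(spatial_phase_lag(empty, spec), "no decoded positions")
})

test_that("asynchrony diagnostics are near zero for independent trains", {
  ev <- poisson_events(100, 2, 100, seed = 5)
  d <- asynchrony_diagnostics(ev, 100, bin = 1, n_pairs = 2000, seed = 1)
  expect_lt(abs(d$mean_correlation), 3 * d$se + 0.005)
  expect_lt(abs(mean(d$fano) - 1), 0.1)
  expect_equal(d$n_excluded, 0)
})

test_that("duplicated spike trains are perfectly correlated; silent neurons excluded", {
  base <- poisson_events(1, 3, 50, seed = 7)
  ev <- rbind(base, transform(base, neuron = 2L))
  d <- asynchrony_diagnostics(ev, 3, bin = 1, n_pairs = 200, seed = 2,
                              t_range = c(0, 50))
  expect_equal(d$mean_correlation, 1, tolerance = 1e-12)
  expect_equal(d$n_excluded, 1)    # neuron 3 never fired
  expect_error(asynchrony_diagnostics(base, 1, bin = 100, t_range = c(0, 50)),
               "at least 2 count bins")
})

test_that("track_object insists on a spatial network", {
  expect_error(track_object(list(), disc_stimulus(), duration = 10),
               "spatial_network")
})
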