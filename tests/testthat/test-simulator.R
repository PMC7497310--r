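# Particle simulators: uncoupled population and homogeneous E-I network

test_that("noiseless uncoupled neurons fire with period theta*tau/mu", {
  sim <- run_uncoupled(10, mu = 2, noise = "constant_sigma", sigma2 = 0,
                       theta = 1, tau = 1, duration = 5, dt = 0.01,
                       init = "reset")
  # period theta*tau/mu = 0.5 -> 10 spikes per neuron in 5 time units
  isi <- diff(sim$events$time[sim$events$neuron == 1])
  expect_true(all(abs(isi - 0.5) < 1e-12))
  expect_equal(sum(sim$counts), 10 * 10)
})

test_that("mean ISI approaches theta*tau/mu as noise vanishes", {
  sim <- run_uncoupled(200, mu = 1, noise = "constant_sigma", sigma2 = 1e-6,
                       duration = 20, dt = 0.005, seed = 1, init = "uniform")
  isi <- unlist(tapply(sim$events$time, sim$events$neuron, diff))
  expect_lt(abs(mean(isi) - 1), 0.01)
})

test_that("subthreshold potentials accumulate white-noise variance sigma2*T/tau^2", {
  # huge threshold: pure integration of the noise, var(v) = sigma2 * T / tau^2
  sim <- run_uncoupled(4000, mu = 0, noise = "constant_sigma", sigma2 = 2,
                       theta = 100, tau = 1, duration = 4, dt = 0.01,
                       seed = 2, init = "reset", record_events = FALSE,
                       snapshot_times = 4)
  v <- sim$snapshots[[1]]$v
  expect_equal(mean(v), 0, tolerance = 0.1)
  expect_equal(var(v), 8, tolerance = 0.1)   # 4 sd of the variance estimate
})

test_that("population rate matches mu/(theta*tau) with overshoot-corrected reset", {
  sim <- run_uncoupled(500, mu = 2, noise = "constant_vmr", beta = 1,
                       duration = 20, dt = 0.002, seed = 3,
                       init = "stationary", carry_overshoot = TRUE)
  cnt <- tabulate(sim$events$neuron, nbins = 500)
  rate <- sum(cnt) / (500 * sim$duration)
  se <- sd(cnt) / (sim$duration * sqrt(500))
  expect_lt(abs(rate - 2), 3 * se)
})

test_that("constant-VMR mode rejects negative mean input", {
  expect_error(run_uncoupled(10, mu = function(t) -1, noise = "constant_vmr",
                             duration = 1, dt = 0.01),
               "mu\\(t\\) >= 0")
})

test_that("uncoupled runs are reproducible under a fixed seed", {
  s1 <- run_uncoupled(50, mu = 1, duration = 5, dt = 0.01, seed = 7)
  s2 <- run_uncoupled(50, mu = 1, duration = 5, dt = 0.01, seed = 7)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$v_final, s2$v_final)
})

test_that("rate_trace bins counts into spikes per neuron per time unit", {
  sim <- run_uncoupled(100, mu = 1, duration = 10, dt = 0.01, seed = 4)
  tr <- rate_trace(sim, bin = 0.5)
  expect_equal(nrow(tr), 20)
  expect_equal(mean(tr$r), sum(sim$counts) / (100 * 10), tolerance = 1e-12)
})

test_that("rise_time finds the 90% crossing of a synthetic step response", {
  t <- seq(0.05, 10, by = 0.1)
  r <- ifelse(t < 5, 1, 5 - 4 * exp(-(t[t >= 5] - 5) / 0.5))
  r[t >= 5] <- 5 - 4 * exp(-(t[t >= 5] - 5) / 0.5)
  tr <- data.frame(t = t, r = r)
  # analytic 90% rise time of a tau=0.5 exponential: 0.5 * log(10) = 1.15
  expect_equal(rise_time(tr, t_step = 5, smooth = 0), 0.5 * log(10),
               tolerance = 0.1)
  expect_error(rise_time(tr, t_step = 20), "step time")
})

test_that("network simulation is reproducible and structurally sound", {
  net <- balanced_network(200, q_I = 0.2, p = 0.25,
                          j = matrix(c(0.25, 0.4, -1, -1), 2, 2),
                          f = c(E = 3, I = 2), theta = 15,
                          tau_m = c(E = 15, I = 10), tau_s = c(E = 6, I = 5))
  drv <- feedforward_drive(0.1, vmr_mode = "poisson_like", beta_F = 0.1)
  s1 <- simulate(net, seed = 5, drive = drv, duration = 10)
  s2 <- simulate(net, seed = 5, drive = drv, duration = 10)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$counts, s2$counts)
  expect_equal(colnames(s1$counts), c("E", "I"))
  expect_true(all(s1$events$time > 0 & s1$events$time <= 10))
  expect_true(all(s1$events$neuron >= 1 & s1$events$neuron <= 160))
})

test_that("simulator warns on unbalanced parameters and coarse steps", {
  net <- balanced_network(100, q_I = 0.2, p = 0.25,
                          j = matrix(c(0.25, 0.4, -1, -1), 2, 2),
                          f = c(E = 1, I = 2), theta = 15,
                          tau_m = c(E = 15, I = 10), tau_s = c(E = 6, I = 5))
  drv <- feedforward_drive(0.1, vmr_mode = "poisson_like", beta_F = 0.1)
  expect_warning(simulate(net, seed = 1, drive = drv, duration = 1),
                 "balance condition")
  net2 <- balanced_network(100, q_I = 0.2, p = 0.25,
                           j = matrix(c(0.25, 0.4, -1, -1), 2, 2),
                           f = c(E = 3, I = 2), theta = 15,
                           tau_m = c(E = 15, I = 10), tau_s = c(E = 6, I = 5))
  expect_warning(simulate(net2, seed = 1, drive = drv, duration = 4, dt = 2),
                 "under-resolved")
})

test_that("feedforward drive validates the constant-sigma mode", {
  expect_error(feedforward_drive(1, vmr_mode = "constant_sigma"), "sigma2_F")
  d <- feedforward_drive(1, vmr_mode = "constant_beta", beta_F = 0.2)
  expect_equal(d$vmr_mode, "poisson_like")
})
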