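# Spatially local network: kernels, sampling, balance, Fourier rate maps

fig5_net <- function(nE = 40, nI = 20, nF = 25) {
  spatial_network(
    nE = nE, nI = nI, nF = nF,
    p = matrix(c(0.02, 0.06, 0.08, 0.08, 0.05, 0.025), 2, 3),
    j = matrix(c(80, 40, -320, -320, 140, 93.3), 2, 3),
    A = c(E = 0.02, I = 0.02, F = 0.05),
    tau_s = c(E = 5, I = 2.5, F = 5))
}

fig5_w <- function() {
  matrix(c(1.28, 1.92, -5.12, -5.12), 2, 2,
         dimnames = list(post = c("E", "I"), pre = c("E", "I")))
}

test_that("kernel probability columns sum exactly to the mean out-degree", {
  post <- spatial_layout(20); pre <- spatial_layout(20)
  P <- gaussian_kernel_weights(post, pre, A = 0.1, p_ab = 0.05)
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(colSums(P), rep(0.05 * 400, 400), tolerance = 1e-9)
})

test_that("water-filling preserves out-degrees under heavy clipping", {
  post <- spatial_layout(20); pre <- spatial_layout(20)
  expect_warning(
    P <- gaussian_kernel_weights(post, pre, A = 0.012, p_ab = 0.05),
    "clipped")
  expect_true(all(P >= 0 & P <= 1))
  expect_true(any(P == 1))
  expect_equal(colSums(P), rep(20, 400), tolerance = 1e-9)
})

test_that("a very wide kernel degrades to uniform probability p", {
  post <- spatial_layout(10); pre <- spatial_layout(10)
  P <- gaussian_kernel_weights(post, pre, A = 10, p_ab = 0.3)
  expect_equal(as.numeric(P), rep(0.3, 1e4), tolerance = 0.005)
})

test_that("torus kernels are translation invariant across columns", {
  post <- spatial_layout(12); pre <- spatial_layout(12)
  P <- suppressWarnings(gaussian_kernel_weights(post, pre, A = 0.08, p_ab = 0.1))
  ref <- sort(P[, 1])
  for (jj in c(5, 77, 144))
    expect_equal(sort(P[, jj]), ref, tolerance = 1e-12)
})

test_that("sampled spatial connections are bit-exact j_ab / N", {
  post <- spatial_layout(10); pre <- spatial_layout(10)
  P <- suppressWarnings(gaussian_kernel_weights(post, pre, A = 0.1, p_ab = 0.1))
  J <- sample_spatial_connectivity(P, j_ab = 80, N = 125, seed = 3)
  expect_identical(unique(J@x), 80 / 125)
  Jn <- sample_spatial_connectivity(P, j_ab = 80, N = 125, seed = 3,
                                    no_self = TRUE)
  expect_true(all(Matrix::diag(Jn) == 0))
})

test_that("distance-dependent connection frequencies match the kernel", {
  post <- spatial_layout(12); pre <- spatial_layout(12)
  P <- suppressWarnings(gaussian_kernel_weights(post, pre, A = 0.1, p_ab = 0.1))
  cnt <- matrix(0, 144, 144)
  nrep <- 20
  for (s in seq_len(nrep))
    cnt <- cnt + as.matrix(sample_spatial_connectivity(P, 1, 144, seed = s) != 0)
  d <- sqrt(outer(post$x, pre$x, function(a, b) pmin(abs(a - b), 1 - abs(a - b))^2) +
            outer(post$y, pre$y, function(a, b) pmin(abs(a - b), 1 - abs(a - b))^2))
  bins <- cut(d, seq(0, 0.45, by = 0.05), include.lowest = TRUE)
  for (b in levels(bins)) {
    idx <- which(bins == b)
    expd <- sum(P[idx]) * nrep
    vr <- sum(P[idx] * (1 - P[idx])) * nrep
    if (vr < 1) next
    expect_lt(abs(sum(cnt[idx]) - expd) / sqrt(vr), 4)
  }
})

test_that("the reference spatial parameters satisfy the balance ordering", {
  chk <- check_spatial_balance(fig5_net())
  expect_equal(unname(chk$ratios),
               c(7 / 2.3325, 1, 2 / 3), tolerance = 1e-12)
  expect_true(chk$ratio_ok)
  expect_true(chk$width_ok)
  expect_true(chk$balanced)
})

test_that("balance check fails on bad kernel widths or equal ratios", {
  bad_width <- fig5_net()
  bad_width$A <- c(E = 0.02, I = 0.05, F = 0.05)   # inhibition wider than E
  expect_false(check_spatial_balance(bad_width)$width_ok)
  eq <- fig5_net()
  eq$j["E", "F"] <- 93.3       # drive ratio becomes exactly the inhibition ratio
  eq$p["E", "F"] <- 0.025
  expect_false(check_spatial_balance(eq)$ratio_ok)
})

test_that("a constant input field reproduces the homogeneous limit rates", {
  net <- fig5_net()
  ref <- limit_rates(fig5_w(), 0.1, f = c(E = 7, I = 2.3325))$r
  fr <- fourier_rates(net,
                      matrix(0.7, 40, 40), matrix(0.23325, 40, 40))
  expect_equal(max(abs(fr$r_E - ref[["E"]])), 0, tolerance = 1e-8)
  expect_equal(max(abs(fr$r_I - ref[["I"]])), 0, tolerance = 1e-8)
})

test_that("Fourier rate maps are linear in the input field", {
  net <- fig5_net()
  lay <- net$layouts$E
  d <- pmin(abs(lay$x - 0.5), 1 - abs(lay$x - 0.5))^2 +
       pmin(abs(lay$y - 0.5), 1 - abs(lay$y - 0.5))^2
  bump <- matrix(exp(-d / (2 * 0.12^2)), 40, 40)
  f1 <- fourier_rates(net, 7 * (0.3 + bump), 2.3325 * (0.3 + bump))
  f2 <- fourier_rates(net, 14 * (0.3 + bump), 4.665 * (0.3 + bump))
  expect_equal(f2$r_E, 2 * f1$r_E, tolerance = 1e-10)
  # smooth admissible input gives strictly positive rate maps
  expect_gt(min(f1$r_E), 0)
  expect_gt(min(f1$r_I), 0)
})

test_that("inputs narrower than the recurrent kernels are rejected", {
  net <- fig5_net()
  delta <- matrix(0, 40, 40); delta[20, 20] <- 1
  expect_error(suppressWarnings(fourier_rates(net, 7 * delta, 2.3325 * delta)),
               "inadmissible input")
})

test_that("the feedforward field of a uniform pixel rate is p_aF j_aF N_F / N", {
  net <- fig5_net(20, 10, 13)
  fe <- feedforward_field(net, rep(1, 169), post = "E")
  expect_equal(dim(fe), c(20, 20))
  expect_equal(mean(fe), 0.05 * 140 * 169 / 500, tolerance = 1e-10)
  # kernel clipping against the coarser pixel grid leaves a small ripple
  expect_lt(sd(fe) / mean(fe), 0.2)
  fi <- feedforward_field(net, rep(1, 169), post = "I")
  expect_equal(mean(fi), 0.025 * 93.3 * 169 / 500, tolerance = 1e-10)
})

test_that("spatial simulations are reproducible under a fixed seed", {
  net <- fig5_net(12, 6, 8)
  stim <- disc_stimulus(center = c(0.5, 0.5), radius = 0.2, magnitude = 10,
                        background_mean = 0.5, background_sd = 0.25)
  s1 <- simulate(net, seed = 4, stimulus = stim, duration = 20)
  s2 <- simulate(net, seed = 4, stimulus = stim, duration = 20)
  expect_identical(s1$events, s2$events)
  expect_true(all(s1$events$population %in% c("E", "F")))
})

test_that("uniform drive yields a statistically flat binned rate map", {
  net <- fig5_net()
  set.seed(11)
  acc <- matrix(0, 5, 5)
  for (k in 1:4) {
    sim <- simulate(net, stimulus = function(t) rep(15, 625), duration = 100)
    rm <- rate_map(sim, "E", t_range = c(20, 100))
    blocks <- matrix(0, 5, 5)
    for (i in 1:5) for (jj in 1:5)
      blocks[i, jj] <- mean(rm[(i - 1) * 8 + 1:8, (jj - 1) * 8 + 1:8])
    acc <- acc + blocks / 4
  }
  expect_lt(sd(acc) / mean(acc), 0.2)
})

test_that("simulated disc-stimulus rate maps match the Fourier prediction", {
  net <- fig5_net()
  stim <- disc_stimulus(center = c(0.25, 0.5), radius = 0.15, magnitude = 15)
  # analytic side: pixel-layer mean rates through the feedforward kernels
  lay <- net$layouts$F
  pix <- render_stimulus(stim, 0, lay, noise = FALSE)
  rho <- pix / (net$theta_F * net$tau_F)
  fr <- suppressWarnings(fourier_rates(net,
                      feedforward_field(net, rho, "E"),
                      feedforward_field(net, rho, "I")))
  set.seed(21)
  acc <- matrix(0, 40, 40)
  for (k in 1:6) {
    sim <- simulate(net, stimulus = stim, duration = 150)
    acc <- acc + rate_map(sim, "E", t_range = c(30, 150)) / 6
  }
  bin8 <- function(m) {
    out <- matrix(0, 5, 5)
    for (i in 1:5) for (jj in 1:5)
      out[i, jj] <- mean(m[(i - 1) * 8 + 1:8, (jj - 1) * 8 + 1:8])
    out
  }
  bm <- bin8(acc); bf <- bin8(fr$r_E)
  expect_gt(cor(as.numeric(bm), as.numeric(bf)), 0.9)
  scale <- sum(bm * bf) / sum(bf^2)
  expect_lt(abs(scale - 1), 0.25)
  # the disc region responds much more strongly than the far background
  layE <- net$layouts$E
  d2 <- pmin(abs(layE$x - 0.25), 1 - abs(layE$x - 0.25))^2 +
        pmin(abs(layE$y - 0.5), 1 - abs(layE$y - 0.5))^2
  inside <- mean(acc[d2 < 0.15^2])
  outside <- mean(acc[d2 > 0.35^2])
  expect_gt(inside / max(outside, 1e-9), 2)
})

test_that("spatial_network validates its parameter tables", {
  expect_error(spatial_network(p = matrix(0.1, 2, 2), j = matrix(1, 2, 3),
                               A = c(0.02, 0.02, 0.05)), "2x3")
  p <- matrix(0.05, 2, 3); j <- matrix(c(1, 1, -1, -1, 1, 1), 2, 3)
  expect_error(spatial_network(p = p, j = matrix(c(-1, 1, -1, -1, 1, 1), 2, 3),
                               A = c(0.02, 0.02, 0.05)), ">= 0")
  expect_error(spatial_network(p = p, j = matrix(c(1, 1, 1, -1, 1, 1), 2, 3),
                               A = c(0.02, 0.02, 0.05)), "<= 0")
  expect_error(spatial_network(p = p, j = j, A = c(0, 0.02, 0.05)),
               "positive")
})
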