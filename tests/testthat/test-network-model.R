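# Network model: populations, connectivity, balance condition

fig3_net <- function(N = 1e4) {
  balanced_network(
    N = N, q_I = 0.2, p = 0.25,
    j = matrix(c(0.25, 0.4, -1, -1), 2, 2), f = c(E = 3, I = 2),
    theta = 15, tau_m = c(E = 15, I = 10), tau_s = c(E = 6, I = 5))
}

test_that("population_sizes splits N by the inhibitory fraction", {
  s <- population_sizes(10000, 0.2)
  expect_identical(unname(s), c(8000, 2000))
  expect_named(s, c("E", "I"))
  s2 <- population_sizes(11, 0.2)
  expect_equal(sum(s2), 11)
  expect_equal(unname(s2), c(9, 2))
  expect_error(population_sizes(100, 0), "q_I")
  expect_error(population_sizes(100, 1), "q_I")
})

test_that("population_sizes handles astronomically large N without overflow", {
  s <- population_sizes(1e12, 0.2)
  expect_equal(unname(s), c(8e11, 2e11))
  expect_false(anyNA(s))
})

test_that("balanced_network validates its inputs", {
  expect_error(fig3_net()$nonexistent, NA)
  expect_error(balanced_network(100, p = 1.5, j = matrix(c(1, 1, -1, -1), 2, 2),
                                f = c(E = 2, I = 1), theta = 1,
                                tau_m = c(E = 1, I = 1), tau_s = c(E = 1, I = 1)),
               "probabilities")
  expect_error(balanced_network(100, p = 0.5, j = matrix(c(-1, 1, -1, -1), 2, 2),
                                f = c(E = 2, I = 1), theta = 1,
                                tau_m = c(E = 1, I = 1), tau_s = c(E = 1, I = 1)),
               ">= 0")
  expect_error(balanced_network(100, p = 0.5, j = matrix(c(1, 1, 1, -1), 2, 2),
                                f = c(E = 2, I = 1), theta = 1,
                                tau_m = c(E = 1, I = 1), tau_s = c(E = 1, I = 1)),
               "<= 0")
  expect_error(balanced_network(100, p = 0.5, j = matrix(c(1, 1, -1, -1), 2, 2),
                                f = c(E = 2, I = 1), theta = 0, v0 = 0,
                                tau_m = c(E = 1, I = 1), tau_s = c(E = 1, I = 1)),
               "theta")
})

test_that("sampled connections are bit-exact j_ab / N", {
  net <- balanced_network(100, q_I = 0.5, p = 1,
                          j = matrix(c(2, 2, -2, -2), 2, 2),
                          f = c(E = 2, I = 1), theta = 1,
                          tau_m = c(E = 1, I = 1), tau_s = c(E = 1, I = 1))
  conn <- sample_connectivity(net, seed = 1)
  # p = 1: every off-diagonal pair connected, strength exactly 2/100
  expect_identical(unique(conn$J$EE@x), 0.02)
  expect_identical(unique(conn$J$EI@x), -0.02)
  expect_equal(Matrix::nnzero(conn$J$EE), 50 * 50 - 50)  # no self-connections
  expect_equal(Matrix::nnzero(conn$J$EI), 50 * 50)
  expect_true(all(Matrix::diag(conn$J$EE) == 0))
  expect_true(all(Matrix::diag(conn$J$II) == 0))
})

test_that("in-degrees are binomial with the right mean", {
  net <- balanced_network(500, q_I = 0.2, p = 0.2,
                          j = matrix(c(1, 1, -1, -1), 2, 2),
                          f = c(E = 2, I = 1), theta = 1,
                          tau_m = c(E = 1, I = 1), tau_s = c(E = 1, I = 1))
  K <- mean_indegree(net)
  expect_equal(K["E", "E"], 0.2 * 400, ignore_attr = TRUE)
  degs <- unlist(lapply(1:20, function(s) {
    conn <- sample_connectivity(net, seed = s)
    Matrix::rowSums(conn$J$EI != 0)
  }))
  # mean in-degree from I: p * N_I = 20, binomial sd sqrt(20 * 0.8)
  se <- sqrt(20 * 0.8 / length(degs))
  expect_lt(abs(mean(degs) - 20), 3 * se)
  expect_lt(abs(var(degs) - 20 * 0.8), 0.15 * 20 * 0.8)
})

test_that("connectivity sampling is reproducible under a fixed seed", {
  net <- fig3_net(300)
  c1 <- sample_connectivity(net, seed = 42)
  c2 <- sample_connectivity(net, seed = 42)
  expect_identical(c1$J, c2$J)
})

test_that("mean synaptic weights and balance ratios match hand arithmetic", {
  net <- fig3_net()
  w <- synaptic_weights(net)
  expect_equal(w["E", "E"], 0.25 * 0.25 * 0.8, ignore_attr = TRUE)
  expect_equal(w["E", "I"], 0.25 * (-1) * 0.2, ignore_attr = TRUE)
  expect_equal(w["I", "E"], 0.25 * 0.4 * 0.8, ignore_attr = TRUE)
  expect_equal(w["I", "I"], 0.25 * (-1) * 0.2, ignore_attr = TRUE)
  chk <- check_balance_condition(net)
  expect_equal(unname(chk$ratios), c(1.5, 1, 0.625))
  expect_true(chk$balanced)
})

test_that("balance condition is strict and fails on equal or inverted ratios", {
  net <- fig3_net()
  # equal drive and inhibition ratios: not balanced (strict inequality)
  chk_eq <- check_balance_condition(net, f = c(E = 2, I = 2))
  expect_false(chk_eq$balanced)
  chk_bad <- check_balance_condition(net, f = c(E = 1, I = 2))
  expect_false(chk_bad$balanced)
})

test_that("degenerate weights raise informative errors", {
  w <- synaptic_weights(fig3_net())
  w0 <- w; w0["I", "I"] <- 0
  expect_error(check_balance_condition(w0, f = c(E = 3, I = 2)), "w_II")
  w1 <- w; w1["I", "E"] <- 0
  expect_error(check_balance_condition(w1, f = c(E = 3, I = 2)), "w_IE")
  expect_error(check_balance_condition(w, f = c(E = 3, I = 0)), "f_I")
})

test_that("weights and balance are invariant under rescaling N", {
  n1 <- fig3_net(1000)
  n2 <- fig3_net(4000)
  expect_equal(synaptic_weights(n1), synaptic_weights(n2))
  expect_equal(check_balance_condition(n1)$ratios,
               check_balance_condition(n2)$ratios)
  # in-degrees scale linearly with N
  expect_equal(mean_indegree(n2), 4 * mean_indegree(n1))
})
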