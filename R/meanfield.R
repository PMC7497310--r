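#' Large-N limit firing rates of the balanced state
#'
#' In the N -> infinity limit, the O(N) feedforward and recurrent currents
#' must cancel to O(1), which pins the population rates at
#' \deqn{r_E = \frac{f_E w_{II} - f_I w_{EI}}{w_{EI} w_{IE} - w_{EE} w_{II}}\,\mu_0,
#'       \qquad
#'       r_I = \frac{f_I w_{EE} - f_E w_{IE}}{w_{EI} w_{IE} - w_{EE} w_{II}}\,\mu_0,}
#' independently of the single-neuron transfer function.  Both rates are
#' linear in the input scale \eqn{\mu_0} and positive exactly when the
#' balance inequality holds.
#'
#' @param net A [balanced_network()] (or 2x2 signed weight matrix, in which
#'   case `f` must be given).
#' @param mu0 External input scale \eqn{\mu_0 \ge 0}.
#' @param f Optional feedforward gains overriding `net$f`.
#' @return A list of class `"meanfield_rates"` with elements `r` (named
#'   vector, spikes per time unit per neuron) and `regime = "limit"`.
#' @export
limit_rates <- function(net, mu0, f = NULL) {
  wf <- resolve_wf(net, f)
  r <- rate_solution(wf$w, wf$f, mu0, N = Inf, theta = NA, tau = c(E = NA, I = NA))
  structure(list(r = r, regime = "limit", mu0 = mu0), class = "meanfield_rates")
}

#' Finite-N firing rates for threshold-linear neurons
#'
#' Solves the mean-field self-consistency for non-leaky integrate-and-fire
#' neurons, whose transfer function is threshold-linear
#' \eqn{r_a = \bar I_a/(\theta\tau_a)}: the linear system
#' \deqn{\theta\tau_a r_a = N\,(f_a\mu_0 + w_{aE} r_E + w_{aI} r_I)}
#' yields rates that differ from the large-N limit by O(1/N) corrections
#' while remaining exactly linear in \eqn{\mu_0}:
#' \deqn{r_E = \frac{(f_E w_{II} - f_I w_{EI}) - f_E\theta\tau_I/N}
#'   {(w_{EI}w_{IE}-w_{EE}w_{II}) + \theta(w_{EE}\tau_I + w_{II}\tau_E)/N
#'    - \theta^2\tau_I\tau_E/N^2}\,\mu_0,}
#' and symmetrically for \eqn{r_I}.
#'
#' Only the non-leaky threshold-linear neuron is supported; the correction
#' terms are specific to that transfer function.
#'
#' @inheritParams limit_rates
#' @param N Network size; defaults to `net$N`.
#' @param theta,tau Threshold and membrane time constants; default to the
#'   network's values.
#' @return A `"meanfield_rates"` list with `regime = "finite_N"`.
#' @export
finite_N_rates <- function(net, mu0, N = NULL, f = NULL,
                           theta = NULL, tau = NULL) {
  wf <- resolve_wf(net, f)
  if (is.null(N)) N <- net$N
  if (is.null(theta)) theta <- net$theta
  if (is.null(tau)) tau <- net$tau_m
  tau <- as_named(tau, POPS, "tau")
  r <- rate_solution(wf$w, wf$f, mu0, N = N, theta = theta, tau = tau)
  structure(list(r = r, regime = "finite_N", mu0 = mu0, N = N),
            class = "meanfield_rates")
}

resolve_wf <- function(net, f) {
  if (inherits(net, "balanced_network")) {
    list(w = synaptic_weights(net), f = if (is.null(f)) net$f else as_named(f, POPS, "f"))
  } else {
    if (is.null(f)) stop("'f' is required when passing a weight matrix")
    list(w = as_ab_matrix(net, "w"), f = as_named(f, POPS, "f"))
  }
}

rate_solution <- function(w, f, mu0, N, theta, tau) {
  cEI <- if (is.finite(N)) theta * tau[["I"]] / N else 0
  cIE <- if (is.finite(N)) theta * tau[["E"]] / N else 0
  den <- (w["E", "I"] * w["I", "E"] - w["E", "E"] * w["I", "I"]) +
    w["E", "E"] * cEI + w["I", "I"] * cIE - cEI * cIE
  if (den == 0)
    stop("singular parameters: w_EI*w_IE - w_EE*w_II (with finite-N terms) is zero")
  rE <- ((f[["E"]] * w["I", "I"] - f[["I"]] * w["E", "I"]) - f[["E"]] * cEI) / den * mu0
  rI <- ((f[["I"]] * w["E", "E"] - f[["E"]] * w["I", "E"]) - f[["I"]] * cIE) / den * mu0
  r <- c(E = unname(rE), I = unname(rI))
  if (mu0 > 0 && any(r < 0)) {
    chk <- check_balance_condition(w, f = f)
    stop(sprintf(
      "balance condition violated (negative predicted rate): f_E/f_I = %.4g, |w_EI|/|w_II| = %.4g, w_EE/w_IE = %.4g",
      chk$ratios[["drive"]], chk$ratios[["inhibition"]], chk$ratios[["excitation"]]))
  }
  r
}

#' @export
print.meanfield_rates <- function(x, ...) {
  cat(sprintf("mean-field rates (%s%s): r_E = %.6g, r_I = %.6g  [spikes / time unit]\n",
              x$regime, if (!is.null(x$N) && is.finite(x$N)) sprintf(", N = %g", x$N) else "",
              x$r[["E"]], x$r[["I"]]))
  invisible(x)
}

#' Input-current statistics in the balanced stationary state
#'
#' For a neuron of population `a` the total input current is approximated as
#' Gaussian white noise with mean \eqn{\mu_a} and variance rate
#' \eqn{\sigma_a^2 = j_{aE} w_{aE} r_E + j_{aI} w_{aI} r_I + \sigma_{aF}^2}.
#' Each recurrent variance term is the product of two like-signed factors
#' and therefore non-negative.  The mean is returned in two forms: the
#' uncancelled O(N) sum \eqn{N(w_{aE}r_E + w_{aI}r_I + f_a\mu_F)} and the
#' O(1) residual recovered from the stationary flux identity
#' \eqn{\mu_a = \theta\tau_a r_a}.
#'
#' @param net A [balanced_network()].
#' @param rates Named rate vector `c(E = , I = )` or a `"meanfield_rates"`
#'   object.
#' @param mu_F External signal mean scale.
#' @param sigma2_F Feedforward input variance rate (per-neuron, O(1)); a
#'   single number or named `c(E = , I = )`.
#' @return A list with named vectors `mu` (O(1) stationary mean), `mu_total`
#'   (the O(N) sum), `sigma2` and `beta` (`sigma2 / mu`, `NA` when
#'   `mu <= 0`).
#' @export
input_statistics <- function(net, rates, mu_F, sigma2_F = 0) {
  if (inherits(rates, "meanfield_rates")) rates <- rates$r
  rates <- as_named(rates, POPS, "rates")
  if (any(rates < 0)) stop("'rates' must be non-negative")
  sigma2_F <- as_named(sigma2_F, POPS, "sigma2_F")
  w <- synaptic_weights(net)
  mu <- sigma2 <- mu_total <- numeric(2L); names(mu) <- names(sigma2) <- names(mu_total) <- POPS
  for (a in POPS) {
    mu_total[a] <- net$N * (w[a, "E"] * rates[["E"]] + w[a, "I"] * rates[["I"]] +
                              net$f[[a]] * mu_F)
    mu[a] <- net$theta * net$tau_m[[a]] * rates[[a]]
    var_terms <- net$j[a, ] * w[a, ] * rates
    if (any(var_terms < 0))
      stop("negative variance contribution: inconsistent sign convention in 'j'")
    sigma2[a] <- sum(var_terms) + sigma2_F[[a]]
  }
  beta <- ifelse(mu > 0, sigma2 / mu, NA_real_)
  list(mu = mu, mu_total = mu_total, sigma2 = sigma2, beta = beta)
}

#' Variance-to-mean ratio profile along an input trajectory
#'
#' Evaluates the stationary input VMR \eqn{\beta_a(t) = \sigma_a^2/\mu_a}
#' at the self-consistent rates for each value of the signal mean
#' \eqn{\mu_F(t)}.  When the feedforward noise is Poisson-like
#' (\eqn{\sigma_{aF}^2 \propto \mu_F}), \eqn{\beta_a} is constant in time:
#' this is the optimal noise structure for instantaneous tracking, because
#' the membrane-potential density depends on the input only through
#' \eqn{\beta_a} and therefore never has to re-equilibrate.
#'
#' @param net A [balanced_network()].
#' @param mu_F Numeric vector of signal mean values (all > 0), interpreted
#'   as samples of \eqn{\mu_F(t)}.
#' @param vmr_mode `"poisson_like"` (`sigma2_F = beta_F * mu_F`, constant
#'   VMR by construction) or `"constant_sigma"` (fixed `sigma2_F`).
#' @param beta_F Feedforward VMR used in `"poisson_like"` mode.
#' @param sigma2_F Fixed feedforward variance in `"constant_sigma"` mode.
#' @param tol Relative tolerance for declaring the profile time-constant.
#' @return A list with matrix `beta` (rows = time points, columns E/I) and
#'   logical `constant`.
#' @export
vmr_profile <- function(net, mu_F, vmr_mode = c("poisson_like", "constant_sigma"),
                        beta_F = 1, sigma2_F = 1, tol = 1e-8) {
  vmr_mode <- match.arg(vmr_mode)
  if (any(mu_F <= 0)) stop("VMR undefined: 'mu_F' must be positive throughout")
  beta <- matrix(NA_real_, length(mu_F), 2L, dimnames = list(NULL, POPS))
  for (k in seq_along(mu_F)) {
    r <- finite_N_rates(net, mu_F[k])$r
    s2F <- if (vmr_mode == "poisson_like") beta_F * mu_F[k] else sigma2_F
    beta[k, ] <- input_statistics(net, r, mu_F[k], s2F)$beta
  }
  rng <- apply(beta, 2L, function(col) diff(range(col)) / max(abs(col)))
  list(beta = beta, constant = all(rng <= tol))
}
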