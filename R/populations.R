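#' Define a neural population
#'
#' A population of identical non-leaky linear integrate-and-fire neurons.
#' The membrane potential obeys \eqn{\tau \, dv/dt = I}; when \eqn{v} reaches
#' the threshold \eqn{\theta} the neuron emits a spike and \eqn{v} is reset to
#' \eqn{v_0}.  There is no leak term, so the single-neuron transfer function
#' is threshold-linear: \eqn{r = \max(\bar I, 0) / (\theta \tau)}.
#'
#' @param label Population label, one of `"E"` (excitatory), `"I"`
#'   (inhibitory) or `"F"` (feedforward / pixel layer).
#' @param size Number of neurons (positive integer).
#' @param theta Firing threshold \eqn{\theta > v_0}.
#' @param v0 Reset potential (default 0).
#' @param tau_m Membrane integration time constant \eqn{\tau > 0}.  All time
#'   constants are in the same abstract time unit; rates are reported per
#'   that unit.
#' @param tau_s Synaptic time constant \eqn{\tau_s > 0} of the exponential
#'   synaptic kernel attached to spikes *emitted* by this population.
#' @param reflecting_barrier Logical; if `TRUE`, the membrane potential is
#'   clamped at `v0` from below (no hyperpolarization past the reset value).
#'
#' @return An object of class `"ei_population"`.
#' @examples
#' pop <- ei_population("E", size = 8000, theta = 15, tau_m = 15, tau_s = 6)
#' pop
#' @export
ei_population <- function(label = c("E", "I", "F"), size, theta, v0 = 0,
                          tau_m, tau_s = tau_m, reflecting_barrier = FALSE) {
  label <- match.arg(label)
  size <- as.integer(size)
  if (length(size) != 1L || is.na(size) || size < 0L)
    stop("'size' must be a single non-negative integer")
  if (!is.numeric(theta) || theta <= v0)
    stop("'theta' must exceed the reset potential 'v0'")
  for (nm in c("tau_m", "tau_s")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || val <= 0)
      stop(sprintf("'%s' must be a positive scalar", nm))
  }
  structure(
    list(label = label, size = size, theta = theta, v0 = v0,
         tau_m = tau_m, tau_s = tau_s,
         reflecting_barrier = isTRUE(reflecting_barrier)),
    class = "ei_population")
}

#' @export
print.ei_population <- function(x, ...) {
  cat(sprintf(
    "<ei_population %s> n = %d, theta = %g, v0 = %g, tau_m = %g, tau_s = %g%s\n",
    x$label, x$size, x$theta, x$v0, x$tau_m, x$tau_s,
    if (x$reflecting_barrier) ", reflecting barrier" else ""))
  invisible(x)
}

#' Split a total network size into population sizes
#'
#' Deterministic rounding rule: `N_E = round(q_E * N)` and `N_I = N - N_E`,
#' so that the sizes always sum to `N`.
#'
#' @param N Total number of neurons in the recurrent layer.
#' @param q_I Inhibitory fraction in (0, 1); `q_E = 1 - q_I`.
#' @return Named numeric vector `c(E = N_E, I = N_I)` of whole numbers
#'   (kept as doubles so very large theoretical `N` do not overflow).
#' @export
population_sizes <- function(N, q_I) {
  if (q_I <= 0 || q_I >= 1) stop("'q_I' must lie strictly in (0, 1)")
  nE <- round((1 - q_I) * N)
  c(E = nE, I = round(N) - nE)
}
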