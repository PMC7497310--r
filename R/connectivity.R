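POPS <- c("E", "I")

# coerce a scalar or 2x2 matrix into a (post, pre) matrix over E/I
as_ab_matrix <- function(x, what) {
  if (length(x) == 1L) x <- matrix(x, 2, 2)
  x <- as.matrix(x)
  if (!all(dim(x) == c(2L, 2L)))
    stop(sprintf("'%s' must be a scalar or a 2x2 (post, pre) matrix", what))
  dimnames(x) <- list(post = POPS, pre = POPS)
  x
}

#' Construct a homogeneous E-I balanced network
#'
#' Bundles the parameters of a randomly connected two-population network in
#' the dense-connectivity regime: every ordered neuron pair (post in `a`,
#' pre in `b`) is connected independently with probability `p[a, b]`, and an
#' existing connection has strength exactly `j[a, b] / N`, where `N` is the
#' total network size.  The signed convention is `j[, "E"] >= 0` and
#' `j[, "I"] <= 0`.
#'
#' The derived mean synaptic weights are \eqn{w_{ab} = p_{ab} j_{ab} q_b}
#' and the mean in-degrees \eqn{K_{ab} = p_{ab} N_b}.
#'
#' @param N Total number of neurons.
#' @param q_I Fraction of inhibitory neurons (default 0.2).
#' @param p Connection probabilities, scalar or 2x2 (post, pre) matrix.
#' @param j Synaptic strength coefficients (O(1) scale), scalar or 2x2
#'   (post, pre) matrix; excitatory columns must be non-negative and
#'   inhibitory columns non-positive.
#' @param f Feedforward gains, named vector `c(E = , I = )`.
#' @param theta,v0 Threshold and reset potential (shared by E and I).
#' @param tau_m Membrane time constants, named vector `c(E = , I = )`.
#' @param tau_s Synaptic time constants of the *presynaptic* populations,
#'   named vector `c(E = , I = )`.
#' @param reflecting_barrier Clamp membrane potentials at `v0` from below.
#'
#' @return An object of class `"balanced_network"`.
#' @seealso [check_balance_condition()], [sample_connectivity()],
#'   [limit_rates()], [finite_N_rates()]
#' @examples
#' net <- balanced_network(
#'   N = 10000, q_I = 0.2, p = 0.25,
#'   j = matrix(c(0.25, 0.4, -1, -1), 2, 2), f = c(E = 3, I = 2),
#'   theta = 15, tau_m = c(E = 15, I = 10), tau_s = c(E = 6, I = 5))
#' summary(net)
#' @export
balanced_network <- function(N, q_I = 0.2, p, j, f,
                             theta, v0 = 0,
                             tau_m, tau_s,
                             reflecting_barrier = FALSE) {
  p <- as_ab_matrix(p, "p")
  j <- as_ab_matrix(j, "j")
  if (any(p < 0 | p > 1)) stop("connection probabilities 'p' must lie in [0, 1]")
  if (any(j[, "E"] < 0)) stop("excitatory strengths j[, 'E'] must be >= 0")
  if (any(j[, "I"] > 0)) stop("inhibitory strengths j[, 'I'] must be <= 0")
  f <- as_named(f, POPS, "f")
  tau_m <- as_named(tau_m, POPS, "tau_m")
  tau_s <- as_named(tau_s, POPS, "tau_s")
  if (any(c(tau_m, tau_s) <= 0)) stop("time constants must be positive")
  if (theta <= v0) stop("'theta' must exceed 'v0'")
  sizes <- population_sizes(N, q_I)
  structure(
    list(N = round(N), q = c(E = 1 - q_I, I = q_I), sizes = sizes,
         p = p, j = j, f = f, theta = theta, v0 = v0,
         tau_m = tau_m, tau_s = tau_s,
         reflecting_barrier = isTRUE(reflecting_barrier)),
    class = "balanced_network")
}

as_named <- function(x, nms, what) {
  if (length(x) == 1L) x <- rep(x, length(nms))
  if (is.null(names(x))) names(x) <- nms
  x <- x[nms]
  if (anyNA(x)) stop(sprintf("'%s' must be named over %s", what,
                             paste(nms, collapse = ", ")))
  x
}

#' Mean synaptic weights of a balanced network
#'
#' Returns the matrix \eqn{w_{ab} = p_{ab} j_{ab} q_b} (post `a`, pre `b`),
#' carrying the sign of `j` (so `w[, "I"] <= 0`).
#'
#' @param net A [balanced_network()].
#' @return 2x2 numeric matrix.
#' @export
synaptic_weights <- function(net) {
  w <- net$p * net$j * rep(net$q, each = 2L)
  dimnames(w) <- dimnames(net$p)
  w
}

#' Mean in-degrees of a balanced network
#'
#' @param net A [balanced_network()].
#' @return 2x2 matrix `K[a, b] = p[a, b] * N_b`.
#' @export
mean_indegree <- function(net) {
  K <- net$p * rep(net$sizes, each = 2L)
  dimnames(K) <- dimnames(net$p)
  K
}

#' Check the balanced-state condition
#'
#' The strict double inequality
#' \deqn{f_E / f_I \;>\; |w_{EI}| / |w_{II}| \;>\; w_{EE} / w_{IE}}
#' is necessary and sufficient for a positive, stable balanced firing state
#' in the large-N limit.  Ratios are formed between like-signed quantities,
#' so each reported ratio is positive.
#'
#' @param net A [balanced_network()], or a 2x2 signed weight matrix.
#' @param f Feedforward gains `c(E = , I = )`; defaults to `net$f` when a
#'   network is supplied.
#' @return An object of class `"balance_check"`: a list with `ratios`
#'   (named: `drive`, `inhibition`, `excitation`) and `balanced` (logical).
#' @examples
#' net <- balanced_network(N = 1e4, q_I = 0.2, p = 0.25,
#'   j = matrix(c(0.25, 0.4, -1, -1), 2, 2), f = c(E = 3, I = 2),
#'   theta = 15, tau_m = c(E = 15, I = 10), tau_s = c(E = 6, I = 5))
#' check_balance_condition(net)
#' @export
check_balance_condition <- function(net, f = NULL) {
  if (inherits(net, "balanced_network")) {
    w <- synaptic_weights(net)
    if (is.null(f)) f <- net$f
  } else {
    w <- as_ab_matrix(net, "w")
    if (is.null(f)) stop("'f' is required when passing a weight matrix")
    f <- as_named(f, POPS, "f")
  }
  if (w["I", "I"] == 0) stop("balance ratios undefined: w_II is zero")
  if (w["I", "E"] == 0) stop("balance ratios undefined: w_IE is zero")
  if (f["I"] == 0) stop("balance ratios undefined: f_I is zero")
  ratios <- c(drive      = unname(f["E"] / f["I"]),
              inhibition = abs(w["E", "I"]) / abs(w["I", "I"]),
              excitation = w["E", "E"] / w["I", "E"])
  structure(list(ratios = ratios,
                 balanced = ratios[["drive"]] > ratios[["inhibition"]] &&
                   ratios[["inhibition"]] > ratios[["excitation"]]),
            class = "balance_check")
}

#' @export
print.balance_check <- function(x, ...) {
  r <- x$ratios
  cat(sprintf("f_E/f_I = %.4g  %s  |w_EI|/|w_II| = %.4g  %s  w_EE/w_IE = %.4g\n",
              r[["drive"]], if (r[["drive"]] > r[["inhibition"]]) ">" else "<=",
              r[["inhibition"]],
              if (r[["inhibition"]] > r[["excitation"]]) ">" else "<=",
              r[["excitation"]]))
  cat(if (x$balanced) "balanced firing state condition holds\n"
      else "balance condition VIOLATED\n")
  invisible(x)
}

#' Sample a random connectivity realization
#'
#' Draws, for every ordered population pair, an independent Bernoulli
#' connection matrix with probability `p[a, b]` per pair; existing entries
#' equal exactly `j[a, b] / N`.  Self-connections are excluded.
#'
#' @param net A [balanced_network()].
#' @param seed Integer seed; the same seed reproduces the same matrices.
#' @return A list of class `"ei_connectivity"` with sparse matrices
#'   `J$EE, J$EI, J$IE, J$II` (rows = postsynaptic, columns = presynaptic)
#'   and the seed used.
#' @export
sample_connectivity <- function(net, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  J <- list()
  for (a in POPS) for (b in POPS) {
    J[[paste0(a, b)]] <- sample_bernoulli_matrix(
      net$sizes[[a]], net$sizes[[b]], net$p[a, b],
      net$j[a, b] / net$N, no_self = (a == b))
  }
  structure(list(J = J, N = net$N, seed = seed), class = "ei_connectivity")
}

# Bernoulli(p) sparse matrix with constant nonzero value, optionally
# excluding the diagonal (self-connections)
sample_bernoulli_matrix <- function(nrow, ncol, p, value, no_self = FALSE) {
  if (nrow == 0L || ncol == 0L || p == 0 || value == 0)
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(nrow, ncol)))
  idx <- which(stats::runif(as.double(nrow) * ncol) < p)
  i <- ((idx - 1L) %% nrow) + 1L
  j <- ((idx - 1L) %/% nrow) + 1L
  if (no_self) {
    keep <- i != j
    i <- i[keep]; j <- j[keep]
  }
  Matrix::sparseMatrix(i = i, j = j, x = rep(value, length(i)),
                       dims = c(nrow, ncol))
}

#' @export
print.balanced_network <- function(x, ...) {
  cat(sprintf("<balanced_network> N = %s (E %s / I %s), theta = %g\n",
              format(x$N, scientific = FALSE, big.mark = ""),
              format(x$sizes[["E"]], scientific = FALSE),
              format(x$sizes[["I"]], scientific = FALSE), x$theta))
  invisible(x)
}

#' @export
summary.balanced_network <- function(object, mu0 = NULL, ...) {
  print(object)
  cat(sprintf("tau_m: E %g, I %g   tau_s: E %g, I %g%s\n",
              object$tau_m[["E"]], object$tau_m[["I"]],
              object$tau_s[["E"]], object$tau_s[["I"]],
              if (object$reflecting_barrier) "   (reflecting barrier)" else ""))
  cat("mean weights w_ab = p_ab j_ab q_b:\n")
  print(signif(synaptic_weights(object), 4))
  print(check_balance_condition(object))
  if (!is.null(mu0)) {
    r <- finite_N_rates(object, mu0)
    cat(sprintf("predicted rates at mu0 = %g (finite N): r_E = %.4g, r_I = %.4g\n",
                mu0, r$r["E"], r$r["I"]))
  }
  invisible(object)
}
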