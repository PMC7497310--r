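#' Stationary membrane-potential density
#'
#' Closed-form stationary solution of the membrane-potential Fokker-Planck
#' equation for a non-leaky integrate-and-fire population driven by Gaussian
#' white-noise current with mean \eqn{\mu > 0} and variance rate
#' \eqn{\sigma^2}.  With the VMR \eqn{\beta = \sigma^2/\mu}:
#' \deqn{p^0(v) = \begin{cases}
#'   \frac{1}{\theta}\left(1 - e^{-2\tau\theta/\beta}\right) e^{2\tau v/\beta}, & v < 0\\
#'   \frac{1}{\theta}\left(1 - e^{-2\tau(\theta - v)/\beta}\right), & 0 \le v \le \theta\\
#'   0, & v > \theta.
#' \end{cases}}
#' The density is continuous at \eqn{v = 0}, vanishes at the absorbing
#' threshold \eqn{\theta}, and integrates to 1 analytically.  Note it
#' depends on the input only through \eqn{\beta}.
#'
#' @param mu Mean input current (> 0).
#' @param sigma2 Input variance rate (> 0).
#' @param theta Firing threshold.
#' @param tau Membrane time constant.
#' @param v Optional grid of potentials; defaults to a regular grid of `n`
#'   points on `[v_min, theta]`.
#' @param n,v_min Grid size and lower bound (default `-6 * beta` below the
#'   reset potential, where the exponential tail is negligible).
#' @return An object of class `"fp_density"`: list with `v`, `p` and the
#'   parameters.
#' @examples
#' d <- stationary_density(mu = 1, sigma2 = 1, theta = 1, tau = 1)
#' plot(d)
#' @export
stationary_density <- function(mu, sigma2, theta = 1, tau = 1,
                               v = NULL, n = 2000, v_min = NULL) {
  check_fp_params(theta, tau)
  if (mu <= 0) stop("the stationary form requires mu > 0")
  if (sigma2 <= 0) stop("'sigma2' must be positive")
  beta <- sigma2 / mu
  if (is.null(v)) {
    if (is.null(v_min)) v_min <- -6 * beta
    v <- seq(v_min, theta, length.out = n)
  }
  structure(list(v = v, p = fp_stationary_pdf(v, mu, sigma2, theta, tau),
                 mu = mu, sigma2 = sigma2, beta = beta,
                 theta = theta, tau = tau, t = Inf),
            class = "fp_density")
}

#' @rdname stationary_density
#' @export
fp_stationary_pdf <- function(v, mu, sigma2, theta = 1, tau = 1) {
  beta <- sigma2 / mu
  k <- 2 * tau / beta
  p <- numeric(length(v))
  lo <- v < 0
  mid <- v >= 0 & v <= theta
  p[lo] <- (1 - exp(-k * theta)) * exp(k * v[lo]) / theta
  p[mid] <- (1 - exp(-k * (theta - v[mid]))) / theta
  p
}

#' @rdname stationary_density
#' @export
fp_stationary_cdf <- function(v, mu, sigma2, theta = 1, tau = 1) {
  beta <- sigma2 / mu
  k <- 2 * tau / beta
  E <- exp(-k * theta)
  F0 <- (1 - E) / (theta * k)
  cdf <- numeric(length(v))
  lo <- v < 0
  mid <- v >= 0 & v <= theta
  cdf[lo] <- F0 * exp(k * v[lo])
  cdf[mid] <- F0 + (v[mid] - (exp(-k * (theta - v[mid])) - E) / k) / theta
  cdf[v > theta] <- 1
  cdf
}

#' Sample membrane potentials from the stationary density
#'
#' Inverse-CDF sampling of the closed-form stationary density, used to start
#' particle simulations in (or near) the stationary state.
#'
#' @param nsamp Number of samples.
#' @inheritParams stationary_density
#' @param grid_n Resolution of the numerical inversion grid on `[0, theta]`.
#' @return Numeric vector of potentials.
#' @export
sample_stationary_v <- function(nsamp, mu, sigma2, theta = 1, tau = 1,
                                grid_n = 4096) {
  beta <- sigma2 / mu
  k <- 2 * tau / beta
  E <- exp(-k * theta)
  F0 <- (1 - E) / (theta * k)
  u <- stats::runif(nsamp)
  out <- numeric(nsamp)
  lo <- u <= F0
  out[lo] <- log(u[lo] / F0) / k
  if (any(!lo)) {
    vg <- seq(0, theta, length.out = grid_n)
    Fg <- fp_stationary_cdf(vg, mu, sigma2, theta, tau)
    out[!lo] <- stats::approx(Fg, vg, xout = u[!lo], rule = 2)$y
  }
  out
}

#' Stationary firing rate (threshold flux)
#'
#' The stationary population rate is the probability flux at threshold,
#' \eqn{r = -\frac{\sigma^2}{2\tau^2}\,\partial_v p^0(v)\big|_\theta
#'        = \frac{\mu}{\theta\tau}} for \eqn{\mu \ge 0} (0 otherwise):
#' the threshold-linear transfer function, independent of \eqn{\sigma^2}.
#'
#' @inheritParams stationary_density
#' @param sigma2 Ignored (kept for interface symmetry; the rate does not
#'   depend on it).
#' @return Non-negative rate in spikes per neuron per time unit.
#' @export
stationary_rate <- function(mu, sigma2 = NULL, theta = 1, tau = 1) {
  check_fp_params(theta, tau)
  max(mu, 0) / (theta * tau)
}

check_fp_params <- function(theta, tau) {
  if (theta <= 0) stop("'theta' must be positive")
  if (tau <= 0) stop("'tau' must be positive")
}

#' @export
print.fp_density <- function(x, ...) {
  cat(sprintf("<fp_density> %d grid points on [%.3g, %.3g]%s\n",
              length(x$v), min(x$v), max(x$v),
              if (is.finite(x$t)) sprintf(", t = %g", x$t) else " (stationary)"))
  invisible(x)
}

#' @export
plot.fp_density <- function(x, ...) {
  graphics::plot(x$v, x$p, type = "l", xlab = "membrane potential v",
                 ylab = "density p(v)", ...)
  invisible(x)
}

#' Transient Fokker-Planck solver
#'
#' Integrates the advection-diffusion equation for the membrane-potential
#' density,
#' \deqn{\tau\,\partial_t p = -\mu(t)\,\partial_v p
#'        + \frac{\sigma^2(t)}{2\tau}\,\partial_v^2 p,}
#' with an absorbing boundary at the threshold \eqn{\theta}, reinjection of
#' the absorbed threshold flux at the reset potential, and zero flux at the
#' truncated lower bound.  Discretization: cell-centered finite volume with
#' central-difference fluxes, a one-sided second-order flux at the
#' absorbing face, and a backward-Euler step.  The reinjection source is
#' part of the implicit operator, so total probability is conserved to
#' round-off every step and the scheme's fixed point is the discrete
#' stationary equation (no time-step bias in the steady state).  The
#' instantaneous population rate is the absorbed flux per unit time.
#'
#' The scheme is positivity-preserving when the cell Peclet number
#' \eqn{\mu h / (\sigma^2 / 2\tau)} stays below 2; a warning is issued
#' otherwise.
#'
#' @param mu,sigma2 Input mean and variance rate: scalars or functions of
#'   time.
#' @param theta,tau Threshold and membrane time constant.
#' @param t_end Integration horizon.
#' @param dt Time step.
#' @param n Number of grid cells.
#' @param v_min Lower truncation bound (default `-8 * max(beta)` using the
#'   initial parameters); set `v_min = v_reset` for a hard reflecting
#'   barrier at the reset potential.
#' @param v_reset Reset potential where the threshold flux is reinjected.
#' @param init Initial density: an `"fp_density"`, a function of `v`, or
#'   `NULL` for the stationary density of the initial parameters.
#' @param record_times Times at which to store density snapshots.
#' @return An object of class `"fp_evolution"`: list with `v` (cell
#'   centers), `p` (final density), `rate` (data.frame `t`, `r`),
#'   `densities` (snapshots), and `mass_error` (max per-step deviation of
#'   total probability after reinjection).
#' @export
evolve_density <- function(mu, sigma2, theta = 1, tau = 1, t_end, dt = 0.005,
                           n = 1000, v_min = NULL, v_reset = 0,
                           init = NULL, record_times = numeric()) {
  check_fp_params(theta, tau)
  mu_fun <- if (is.function(mu)) mu else function(t) mu
  s2_fun <- if (is.function(sigma2)) sigma2 else function(t) sigma2
  mu0 <- mu_fun(0); s20 <- s2_fun(0)
  if (s20 <= 0) stop("'sigma2' must be positive")
  if (is.null(v_min)) v_min <- v_reset - 8 * max(s20 / max(mu0, 1e-12), 0.2)
  if (v_min >= v_reset) v_min <- v_reset  # reflecting barrier at reset
  h <- (theta - v_min) / n
  vc <- v_min + (seq_len(n) - 0.5) * h      # cell centers
  # reinjection source: split the delta at v_reset linearly between the
  # two nearest cell centers (alignment-independent, second order)
  i0 <- max(1L, min(n - 1L, floor((v_reset - v_min) / h + 0.5)))
  lam <- min(1, max(0, (v_reset - vc[i0]) / h))
  reset_idx <- c(i0, i0 + 1L)
  reset_w <- c(1 - lam, lam)

  m <- init_mass(init, vc, h, mu0, s20, theta, tau)
  nsteps <- max(1L, round(t_end / dt))
  rate <- numeric(nsteps)
  times <- (seq_len(nsteps)) * dt
  snapshots <- list()
  rec <- sort(record_times)
  mass_err <- 0
  cur <- c(NA_real_, NA_real_)
  op <- NULL
  warned_peclet <- FALSE

  for (s in seq_len(nsteps)) {
    t0 <- (s - 1L) * dt
    pars <- c(mu_fun(t0), s2_fun(t0))
    if (!identical(pars, cur)) {
      cur <- pars
      adv <- cur[1] / tau
      D <- cur[2] / (2 * tau^2)
      if (!warned_peclet && adv * h / D > 2) {
        warning(sprintf("cell Peclet number %.2f > 2: refine the grid for positivity",
                        adv * h / D))
        warned_peclet <- TRUE
      }
      op <- fp_operator_factor(n, h, adv, D, dt, reset_idx, reset_w)
    }
    tot0 <- sum(m)
    m <- as.numeric(Matrix::solve(op$fac, m))
    if (min(m) < -1e-8 * max(m))
      stop("instability detected (negative density): reduce 'dt' or refine grid")
    mass_err <- max(mass_err, abs(sum(m) - tot0))
    rate[s] <- sum(op$flux * m[op$flux_idx])   # absorbed flux at threshold
    while (length(rec) && rec[1] <= s * dt + 1e-12) {
      snapshots[[length(snapshots) + 1L]] <- structure(
        list(v = vc, p = m / h, t = rec[1], theta = theta, tau = tau),
        class = "fp_density")
      rec <- rec[-1]
    }
  }
  structure(list(v = vc, p = m / h, h = h,
                 rate = data.frame(t = times, r = rate),
                 densities = snapshots, mass_error = mass_err,
                 theta = theta, tau = tau, v_min = v_min, dt = dt),
            class = "fp_evolution")
}

init_mass <- function(init, vc, h, mu0, s20, theta, tau) {
  p <- if (is.null(init)) {
    if (mu0 <= 0) stop("need mu(0) > 0 to start from the stationary density")
    fp_stationary_pdf(vc, mu0, s20, theta, tau)
  } else if (inherits(init, "fp_density")) {
    stats::approx(init$v, init$p, xout = vc, rule = 2)$y
  } else if (is.function(init)) {
    init(vc)
  } else stop("'init' must be NULL, an fp_density, or a function of v")
  m <- p * h
  m / sum(m)
}

# backward-Euler operator (I - dt * L) for the finite-volume
# discretization, including the implicit reinjection source, returned
# factorized for repeated solves.  The absorbing-face diffusive flux uses
# the quadratic one-sided stencil through p(theta) = 0:
#   F_top = dC * (9 m_n - m_{n-1}) / 3.
fp_operator_factor <- function(n, h, adv, D, dt, reset_idx, reset_w) {
  aP <- adv / (2 * h)   # advective half-flux coefficient
  dC <- D / h^2
  lower <- rep(aP + dC, n - 1L)              # coupling to cell below
  upper <- rep(-aP + dC, n - 1L)             # coupling to cell above
  diag0 <- rep(-2 * dC, n)
  diag0[1L] <- -aP - dC                       # zero-flux bottom face
  # absorbing top face: interior flux below + one-sided outgoing flux
  diag0[n] <- (aP - dC) - 3 * dC
  lower[n - 1L] <- lower[n - 1L] + dC / 3
  ii <- c(seq_len(n), seq_len(n - 1L), seq_len(n - 1L) + 1L)
  jj <- c(seq_len(n), seq_len(n - 1L) + 1L, seq_len(n - 1L))
  xx <- c(diag0, upper, lower)
  # implicit reinjection of the absorbed flux into the reset cells
  flux_idx <- c(n, n - 1L)
  flux <- c(3 * dC, -dC / 3)
  ii <- c(ii, rep(reset_idx, each = 2L))
  jj <- c(jj, rep(flux_idx, times = 2L))
  xx <- c(xx, as.vector(outer(flux, reset_w)))
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  A <- Matrix::Diagonal(n) - dt * L
  list(fac = Matrix::lu(A), flux = flux, flux_idx = flux_idx)
}

#' @export
print.fp_evolution <- function(x, ...) {
  cat(sprintf("<fp_evolution> %d cells, %d steps (dt = %g), final rate %.5g, max mass error %.2e\n",
              length(x$v), nrow(x$rate), x$dt, utils::tail(x$rate$r, 1),
              x$mass_error))
  invisible(x)
}

#' @export
plot.fp_evolution <- function(x, what = c("rate", "density"), ...) {
  what <- match.arg(what)
  if (what == "rate")
    graphics::plot(x$rate$t, x$rate$r, type = "l", xlab = "time",
                   ylab = "population rate", ...)
  else
    graphics::plot(x$v, x$p, type = "l", xlab = "membrane potential v",
                   ylab = "density p(v)", ...)
  invisible(x)
}
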