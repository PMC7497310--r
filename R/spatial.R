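SPAT_PRE <- c("E", "I", "F")

#' Gaussian connection-probability kernel between two layers
#'
#' Builds the (post, pre) connection-probability matrix for distance-
#' dependent connectivity: the unnormalized kernel is
#' \eqn{\exp(-d_{ij}^2 / (2 A_b^2))} with `A_b` the presynaptic
#' population's spatial scale (standard deviation), each presynaptic
#' column is normalized to sum 1 over the postsynaptic layer, and the
#' result is scaled by `p_ab * N_post` so that the population-averaged
#' pairwise probability equals `p_ab` and the expected number of
#' connections made by each presynaptic neuron is `p_ab * N_post` (the
#' homogeneous in-degree `p_ab * N_pre` is recovered on average).
#'
#' When the kernel is narrow relative to the grid, the scaled entries can
#' exceed 1.  They are clipped to 1 and the clipped-off mass is
#' redistributed over the remaining entries of the same column
#' (water-filling), so each presynaptic neuron keeps its expected
#' out-degree `p_ab * N_post` exactly and the population-averaged pairwise
#' probability stays `p_ab`; a warning reports how many entries were
#' clipped.  Without the redistribution, plain clipping would silently
#' shrink the out-degrees (strongly so for dense local projections),
#' breaking the excitation-inhibition weight ratios the balanced state
#' relies on.
#'
#' @param post,pre [spatial_layout()]s of the post- and presynaptic layers.
#' @param A Gaussian scale parameter of the presynaptic population (> 0).
#' @param p_ab Target average connection probability.
#' @param torus Wrapped (translation-invariant) distances; `FALSE` uses
#'   open boundaries.
#' @return N_post x N_pre probability matrix.
#' @export
gaussian_kernel_weights <- function(post, pre, A, p_ab, torus = TRUE) {
  if (A <= 0) stop("kernel scale 'A' must be positive")
  if (p_ab < 0 || p_ab > 1) stop("'p_ab' must lie in [0, 1]")
  if (p_ab == 0 || nrow(post) == 0L || nrow(pre) == 0L)
    return(matrix(0, nrow(post), nrow(pre)))
  G <- exp(-dist2_xy(post$x, post$y, pre$x, pre$y, torus = torus) / (2 * A^2))
  G <- sweep(G, 2L, colSums(G), "/")          # per-presynaptic normalization
  K <- p_ab * nrow(post)                      # target out-degree per column
  P <- K * G
  if (any(P > 1)) {
    n_over <- sum(P > 1)
    for (jj in which(colSums(P > 1) > 0L))
      P[, jj] <- waterfill_column(G[, jj], K)
    warning(sprintf(
      "connection probabilities clipped at 1 for %d of %d entries (narrow kernel); clipped mass redistributed to preserve out-degrees",
      n_over, length(P)))
  }
  P
}

# clip a scaled kernel column at 1 while preserving its sum: the k largest
# entries saturate at 1 and the rest are rescaled so that
# sum(pmin(s * g, 1)) = K (water-filling); g >= 0 with sum 1
waterfill_column <- function(g, K) {
  n <- length(g)
  if (K >= n) return(rep(1, n))
  o <- order(g, decreasing = TRUE)
  gs <- g[o]
  # tail mass summed directly (a 1 - cumsum(head) form cancels
  # catastrophically for narrow kernels and breaks the column-sum identity)
  tail_mass <- rev(cumsum(rev(gs)))
  k <- 0L; s <- K / tail_mass[1L]
  while (k < n - 1L && k < K && gs[k + 1L] > 0 && s * gs[k + 1L] > 1) {
    k <- k + 1L
    rem <- tail_mass[k + 1L]
    if (rem <= 0) { s <- Inf; break }
    s <- (K - k) / rem
  }
  if (!is.finite(s)) {
    # the kernel's numeric support holds less mass than the target
    # out-degree: connect the K nearest pairs outright
    p <- numeric(n)
    kk <- floor(K)
    p[o[seq_len(kk)]] <- 1
    if (K > kk) p[o[kk + 1L]] <- K - kk
    return(p)
  }
  p <- pmin(s * g, 1)
  p[o[seq_len(k)]] <- 1
  p
}

#' Sample connectivity with per-pair probabilities
#'
#' As [sample_connectivity()] but with an arbitrary probability matrix
#' (from [gaussian_kernel_weights()]); existing connections have strength
#' exactly `j_ab / N`.
#'
#' @param P Probability matrix (post x pre).
#' @param j_ab Strength coefficient.
#' @param N Weight-scaling network size (the balanced layer's total size).
#' @param seed Optional seed.
#' @param no_self Exclude the diagonal.
#' @return Sparse (post x pre) weight matrix.
#' @export
sample_spatial_connectivity <- function(P, j_ab, N, seed = NULL,
                                        no_self = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  idx <- which(stats::runif(length(P)) < P)
  i <- ((idx - 1L) %% nrow(P)) + 1L
  j <- ((idx - 1L) %/% nrow(P)) + 1L
  if (no_self) { keep <- i != j; i <- i[keep]; j <- j[keep] }
  Matrix::sparseMatrix(i = i, j = j, x = rep(j_ab / N, length(i)),
                       dims = dim(P))
}

#' Construct a spatially structured E-I balanced network
#'
#' The locally connected extension: every layer lives on the unit square,
#' and the probability that presynaptic neuron `j` (population `b` in E,
#' I, F) connects to postsynaptic neuron `i` (population `a` in E, I)
#' decays with distance as a Gaussian of scale `A[b]`.  Connection
#' strengths are `j[a, b] / N` with `N` the balanced layer's total size.
#' The feedforward layer `F` is the event-camera pixel grid.
#'
#' @param nE,nI,nF Grid dimensions (side lengths) of the E, I and pixel
#'   layers; the full-scale reference configuration is 80 / 40 / 50.
#' @param p 2x3 (post = E,I; pre = E,I,F) connection-probability matrix.
#' @param j 2x3 strength matrix (columns E, F non-negative, I
#'   non-positive).
#' @param A Kernel scales `c(E = , I = , F = )`; balanced configurations
#'   need `A_F > A_E >= A_I`.
#' @param theta Threshold of E and I neurons.
#' @param tau_m Membrane constants `c(E = , I = )`.
#' @param tau_s Synaptic constants of the presynaptic populations
#'   `c(E = , I = , F = )`.
#' @param tau_F,theta_F Pixel membrane constant and threshold.
#' @param reflecting_barrier Clamp balanced-layer potentials at 0.
#' @param torus Wrapped distances (translation invariant); `FALSE` for
#'   open boundaries.
#' @return An object of class `"spatial_network"`.
#' @export
spatial_network <- function(nE = 40, nI = 20, nF = 25,
                            p, j, A,
                            theta = 15,
                            tau_m = c(E = 15, I = 10),
                            tau_s = c(E = 5, I = 2.5, F = 5),
                            tau_F = 1, theta_F = 15,
                            reflecting_barrier = TRUE, torus = TRUE) {
  p <- as_spatial_matrix(p, "p"); j <- as_spatial_matrix(j, "j")
  if (any(p < 0 | p > 1)) stop("connection probabilities 'p' must lie in [0, 1]")
  if (any(j[, c("E", "F")] < 0)) stop("excitatory strengths must be >= 0")
  if (any(j[, "I"] > 0)) stop("inhibitory strengths must be <= 0")
  A <- as_named(A, SPAT_PRE, "A")
  if (any(A <= 0)) stop("kernel scales 'A' must be positive")
  tau_m <- as_named(tau_m, POPS, "tau_m")
  tau_s <- as_named(tau_s, SPAT_PRE, "tau_s")
  layouts <- list(E = spatial_layout(nE), I = spatial_layout(nI),
                  F = spatial_layout(nF))
  sizes <- vapply(layouts, nrow, integer(1))
  N <- sizes[["E"]] + sizes[["I"]]
  structure(list(layouts = layouts, sizes = sizes, N = N,
                 q = c(E = sizes[["E"]] / N, I = sizes[["I"]] / N),
                 p = p, j = j, A = A, theta = theta,
                 tau_m = tau_m, tau_s = tau_s,
                 tau_F = tau_F, theta_F = theta_F,
                 reflecting_barrier = isTRUE(reflecting_barrier),
                 torus = isTRUE(torus)),
            class = "spatial_network")
}

as_spatial_matrix <- function(x, what) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(2L, 3L)))
    stop(sprintf("'%s' must be a 2x3 (post = E,I; pre = E,I,F) matrix", what))
  dimnames(x) <- list(post = POPS, pre = SPAT_PRE)
  x
}

#' @export
print.spatial_network <- function(x, ...) {
  cat(sprintf("<spatial_network> E %dx%d, I %dx%d, pixels %dx%d (N = %d), %s\n",
              attr(x$layouts$E, "nx"), attr(x$layouts$E, "ny"),
              attr(x$layouts$I, "nx"), attr(x$layouts$I, "ny"),
              attr(x$layouts$F, "nx"), attr(x$layouts$F, "ny"), x$N,
              if (x$torus) "torus" else "open boundaries"))
  invisible(x)
}

#' Sample the connectivity of a spatial network
#'
#' Draws all six connection matrices (E,I posts x E,I,F pres) using
#' [gaussian_kernel_weights()] and [sample_spatial_connectivity()].
#'
#' @param net A [spatial_network()].
#' @param seed Optional seed.
#' @return List of class `"ei_connectivity"` with sparse matrices `J$EE`,
#'   `J$EI`, `J$EF`, `J$IE`, `J$II`, `J$IF`.
#' @export
sample_spatial_network <- function(net, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  J <- list()
  for (a in POPS) for (b in SPAT_PRE) {
    P <- suppressWarnings(gaussian_kernel_weights(
      net$layouts[[a]], net$layouts[[b]], net$A[[b]], net$p[a, b],
      torus = net$torus))
    J[[paste0(a, b)]] <- sample_spatial_connectivity(
      P, net$j[a, b], net$N, no_self = (a == b))
  }
  structure(list(J = J, N = net$N, seed = seed), class = "ei_connectivity")
}

#' Check the spatial balance conditions
#'
#' Verifies (i) the strict ratio ordering of spatially averaged weights,
#' \eqn{\bar f_E/\bar f_I > \bar w_{EI}/\bar w_{II} > \bar w_{EE}/\bar
#' w_{IE}} (magnitudes; the spatial average of the normalized kernel drops
#' out, leaving \eqn{\bar w_{ab} = q_b j_{ab} p_{ab}} and feedforward
#' averages proportional to \eqn{j_{aF} p_{aF}}), and (ii) the kernel
#' width ordering \eqn{A_F > A_E \ge A_I} required for the feedforward
#' input to be wider than the recurrent interactions.
#'
#' @param net A [spatial_network()].
#' @return List with `ratios`, per-condition logicals `ratio_ok`,
#'   `width_ok`, and overall `balanced`.
#' @export
check_spatial_balance <- function(net) {
  w <- net$p[, POPS] * net$j[, POPS] * rep(net$q, each = 2L)
  fbar <- abs(net$p[, "F"] * net$j[, "F"])
  if (w["I", "I"] == 0 || w["I", "E"] == 0 || fbar[["I"]] == 0)
    stop("spatial balance ratios undefined: zero w_II, w_IE or f_I")
  ratios <- c(drive      = fbar[["E"]] / fbar[["I"]],
              inhibition = abs(w["E", "I"]) / abs(w["I", "I"]),
              excitation = w["E", "E"] / w["I", "E"])
  ratio_ok <- ratios[["drive"]] > ratios[["inhibition"]] &&
    ratios[["inhibition"]] > ratios[["excitation"]]
  width_ok <- net$A[["F"]] > net$A[["E"]] && net$A[["E"]] >= net$A[["I"]]
  list(ratios = ratios, ratio_ok = ratio_ok, width_ok = width_ok,
       balanced = ratio_ok && width_ok)
}

#' Mean-field rate maps of the spatial network by 2-D Fourier transform
#'
#' In the large-N limit the spatially resolved balance condition
#' \eqn{w_{aE} * r_E(x) + w_{aI} * r_I(x) + f_a(x) \to 0} is solved per
#' spatial frequency:
#' \deqn{\tilde r_E = \frac{\tilde f_E \tilde w_{II} - \tilde f_I \tilde w_{EI}}
#'   {\tilde w_{EI}\tilde w_{IE} - \tilde w_{EE}\tilde w_{II}},\qquad
#'   \tilde r_I = \frac{\tilde f_I \tilde w_{EE} - \tilde f_E \tilde w_{IE}}
#'   {\tilde w_{EI}\tilde w_{IE} - \tilde w_{EE}\tilde w_{II}},}
#' with \eqn{\tilde w_{ab}(k) = q_b j_{ab} p_{ab} \tilde G_b(k)} and
#' \eqn{\tilde G_b} the transform of the grid-normalized Gaussian kernel.
#' Inputs and outputs live on the excitatory grid; the torus topology
#' makes the kernels translation invariant so the FFT applies exactly.
#'
#' The input fields must be spectrally wider than the recurrent kernels
#' for the solution to be admissible; a high-frequency blow-up of
#' \eqn{|\tilde r|} triggers an error, and negative real-space rates a
#' balance diagnostic warning.
#'
#' @param net A [spatial_network()].
#' @param f_E,f_I Feedforward mean-field maps on the E grid (matrices
#'   nx x ny, in the same units as `f_a(x)` of the field equation).
#' @param tol Relative tolerance for the near-singular denominator check.
#' @return List of class `"fourier_rates"` with real-space rate matrices
#'   `r_E`, `r_I` and the frequency-domain pieces.
#' @export
fourier_rates <- function(net, f_E, f_I, tol = 1e-12) {
  nx <- attr(net$layouts$E, "nx"); ny <- attr(net$layouts$E, "ny")
  f_E <- as.matrix(f_E); f_I <- as.matrix(f_I)
  if (!all(dim(f_E) == c(nx, ny)) || !all(dim(f_I) == c(nx, ny)))
    stop("input fields must be matrices on the excitatory grid")
  if (!net$torus)
    warning("Fourier solution assumes translation invariance; torus mode recommended")
  G <- lapply(POPS, function(b) kernel_map(net, b))
  names(G) <- POPS
  wt <- list()
  for (b in POPS)
    wt[[b]] <- net$q[[b]] * net$j[, b] * net$p[, b]  # named by post E/I
  Gt <- lapply(G, stats::fft)
  wEEt <- wt$E[["E"]] * Gt$E; wIEt <- wt$E[["I"]] * Gt$E
  wEIt <- wt$I[["E"]] * Gt$I; wIIt <- wt$I[["I"]] * Gt$I
  den <- wEIt * wIEt - wEEt * wIIt
  fEt <- stats::fft(f_E); fIt <- stats::fft(f_I)
  near <- Mod(den) < tol * max(Mod(den))
  if (any(near)) {
    fmax <- max(Mod(fEt), Mod(fIt))
    if (any(Mod(fEt[near]) + Mod(fIt[near]) > 1e-8 * fmax))
      warning("input power at near-singular spatial frequencies; rates may be inaccurate")
  }
  rEt <- (fEt * wIIt - fIt * wEIt) / den
  rIt <- (fIt * wEEt - fEt * wIEt) / den
  # frequencies where the input is numerically zero carry no signal; zero
  # them instead of amplifying roundoff through the small denominator
  fmax <- max(Mod(fEt), Mod(fIt))
  floor_k <- Mod(fEt) < 1e-12 * fmax & Mod(fIt) < 1e-12 * fmax
  rEt[floor_k] <- 0 + 0i
  rIt[floor_k] <- 0 + 0i
  # admissibility: the rate spectrum must decay at high |k|
  hi <- high_freq_mask(nx, ny)
  for (rt in list(rEt, rIt)) {
    if (mean(Mod(rt)[hi]) > mean(Mod(rt)[!hi]))
      stop("inadmissible input: rate spectrum does not decay (input narrower than recurrent kernels)")
  }
  npx <- nx * ny
  r_E <- Re(stats::fft(rEt, inverse = TRUE)) / npx
  r_I <- Re(stats::fft(rIt, inverse = TRUE)) / npx
  if (min(r_E) < -1e-4 * max(abs(r_E)) || min(r_I) < -1e-4 * max(abs(r_I)))
    warning("balance violated at this input: negative predicted rates")
  structure(list(r_E = r_E, r_I = r_I, rEt = rEt, rIt = rIt, den = den),
            class = "fourier_rates")
}

# normalized Gaussian kernel of presynaptic population b evaluated on the
# E grid, centered at the origin cell (wrap-around layout for the FFT)
kernel_map <- function(net, b) {
  nx <- attr(net$layouts$E, "nx"); ny <- attr(net$layouts$E, "ny")
  dx <- (seq_len(nx) - 1) / nx; dx <- pmin(dx, 1 - dx)
  dy <- (seq_len(ny) - 1) / ny; dy <- pmin(dy, 1 - dy)
  G <- exp(-outer(dx^2, dy^2, "+") / (2 * net$A[[b]]^2))
  G / sum(G)
}

high_freq_mask <- function(nx, ny) {
  kx <- c(seq_len(nx) - 1); kx <- pmin(kx, nx - kx) / nx
  ky <- c(seq_len(ny) - 1); ky <- pmin(ky, ny - ky) / ny
  outer(kx, ky, function(a, b) pmax(a, b)) > 0.35
}

#' Expected feedforward mean-field map
#'
#' Computes, on the excitatory grid, the expected feedforward drive
#' \eqn{f_a(x) = \frac{1}{N}\,\mathrm{E}\big[\sum_j P_{ij} (j_{aF}/N) N
#' \rho_j\big] = \frac{j_{aF}}{N} \sum_j P_{ij}\rho_j}
#' produced by pixel firing-rate map `rho` through the sampled Gaussian
#' feedforward kernel, in the units of [fourier_rates()] inputs.  The
#' field is evaluated on the excitatory grid (the common mean-field grid
#' of [fourier_rates()]) for either postsynaptic population: per-pair
#' kernel probabilities are independent of the evaluation grid's density,
#' so the continuum field does not depend on which grid carries it.
#'
#' @param net A [spatial_network()].
#' @param rho Pixel rate vector over the F layout (spikes per time unit).
#' @param post Postsynaptic population `"E"` or `"I"` (selects the gains
#'   `p[post, "F"]`, `j[post, "F"]`).
#' @return Matrix on the excitatory grid.
#' @export
feedforward_field <- function(net, rho, post = "E") {
  P <- suppressWarnings(gaussian_kernel_weights(
    net$layouts$E, net$layouts$F, net$A[["F"]], net$p[post, "F"],
    torus = net$torus))
  val <- as.numeric(P %*% rho) * net$j[post, "F"] / net$N
  matrix(val, attr(net$layouts$E, "nx"), attr(net$layouts$E, "ny"))
}
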