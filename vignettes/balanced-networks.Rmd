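---
title: "Balanced spiking networks as fast signal detectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balanced spiking networks as fast signal detectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette describes the model implemented by **einet**, the numerical
choices behind the simulator and solvers, what the synthetic event-camera
front end does and does not emulate, and the package's known limitations.
Code chunks are shown but not evaluated at build time; every quantitative
statement below is checked by the test suite or computed by
`scripts/acceptance.R`.

## 1. The neuron and the uncoupled population

Each neuron is a non-leaky linear integrate-and-fire unit:

$$\tau_a \frac{dv_i}{dt} = I_i(t), \qquad v_i \ge \theta \Rightarrow
\text{spike},\; v_i \leftarrow v_0,$$

optionally with a reflecting barrier at $v_0$. Without leak, the stationary
firing rate of an uncoupled population driven by mean input $\mu$ is
threshold-linear and noise-independent, $r = \max(\mu, 0)/(\theta\tau)$.

The membrane-potential density $p(v,t)$ obeys an advection–diffusion
Fokker–Planck equation with drift $\mu/\tau$, diffusion
$\sigma^2/(2\tau^2)$, an absorbing boundary at $\theta$, and reinjection of
the threshold flux at $v_0$. Its stationary solution is closed-form
(`fp_stationary_pdf()`, `fp_stationary_cdf()`), controlled by the
variance-to-mean ratio (VMR) $\beta = \sigma^2/\mu$; at
$\mu = \sigma^2 = \theta = \tau = 1$ the density at the reset is
$1 - e^{-2} \approx 0.8647$.

The key dynamical fact is the role of the *noise structure*: if the input
noise keeps a constant VMR (variance proportional to the mean, as for
Poisson-like shot noise), the density profile is invariant under input
steps and the population rate responds essentially instantaneously; with
constant $\sigma^2$, the profile must re-equilibrate first. The test suite
measures a $\ge 5\times$ faster 90% rise time for constant VMR, in both the
particle simulation and the Fokker–Planck transient solver.

```{r}
library(einet)
sim <- run_uncoupled(2500, mu = 1, noise = "constant_vmr", beta = 1,
                     duration = 10, seed = 1, init = "stationary")
ev  <- evolve_density(1, 1, t_end = 10)     # transient FP solve
```

## 2. The balanced recurrent network

`balanced_network()` defines dense random connectivity: population $b$
connects to population $a$ with probability $p_{ab}$ and weight
$j_{ab}/N$ (stored bit-exactly), so the effective mean-field weights are
$w_{ab} = p_{ab}\, j_{ab}\, q_b$ with population fractions $q_b$. The
balanced state requires the strict ordering

$$\frac{f_E}{f_I} > \frac{|w_{EI}|}{|w_{II}|} > \frac{w_{EE}}{w_{IE}},$$

checked by `check_balance_condition()`. Self-consistency
$\theta\tau_a r_a = N(f_a\mu_F + \sum_b w_{ab} r_b)$ gives the firing
rates: `limit_rates()` solves the cancellation condition of the large-$N$
limit, and `finite_N_rates()` retains the $O(1/N)$ left-hand side, which
noticeably suppresses rates at the reduced scales used for testing
($r_E = 2.33$ versus the limit $3.33$ at $N = 2000$, $\mu_F = 0.1$).

## 3. The spatial network and its Fourier solution

`spatial_network()` places E, I, and pixel (F) populations on unit-square
grids with periodic boundaries. Connection probabilities follow Gaussian
kernels of width $A_b$, normalized so that each presynaptic neuron keeps
the homogeneous mean out-degree $p_{ab} N_{\text{post}}$. Where the
requested probability exceeds 1 near the kernel center, probabilities are
clipped and the surplus redistributed outward ("water-filling") so column
sums — and hence mean in-degrees — are preserved exactly.

Spatial balance additionally requires the kernel-width ordering
$A_F > A_E \ge A_I$. For admissible (kernel-smooth, positive) input fields
the stationary rate fields solve a linear system per spatial frequency;
`fourier_rates()` implements this 2-D Fourier solution and rejects inputs
narrower than the recurrent kernels, for which the balanced solution would
be negative.

## 4. The event-camera front end

`spike_camera_encode()` emulates an integrate-and-fire pixel array: each
pixel integrates absolute luminance with time constant $\tau_F$ and emits a
spike on reaching $\theta_F$, so intensity maps to spike rate
$\rho = L/(\theta_F \tau_F)$. This captures the *rate-coding of absolute
intensity* that the downstream network consumes. It does **not** model
sensor non-idealities — dark current, refractoriness, pixel mismatch,
quantal shot noise, or finite readout bandwidth; stimulus realism is limited
to moving discs (static, linear, circular, or sinusoidally modulated
trajectories) with optional clipped-Gaussian background noise.

```{r}
stim <- disc_stimulus(center = c(0.5, 0.5), radius = 0.05, magnitude = 10,
                      trajectory = "circular", orbit_radius = 0.2,
                      period = 200)
net  <- spatial_network(nE = 40, nI = 20, nF = 25,
                        p = matrix(c(0.02, 0.06, 0.08, 0.08, 0.05, 0.025), 2, 3),
                        j = matrix(c(80, 40, -320, -320, 140, 93.3), 2, 3),
                        A = c(E = 0.02, I = 0.02, F = 0.05))
trk  <- track_object(net, stim, duration = 400, n_trials = 5, seed = 1)
```

## 5. Numerical choices

- **Integration.** Forward-Euler stepping with exponentially filtered
  synaptic traces; spikes are detected per step and the membrane is reset to
  $v_0$ (or, with `carry_overshoot = TRUE`, to $v_0$ plus the overshoot,
  which removes the $O(dt)$ downward rate bias — used where an unbiased
  rate estimate is required). Default steps resolve the fastest synaptic
  time constant; the simulator warns when a step is under-resolved.
- **Randomness.** One R RNG stream per run, seeded via `seed` arguments;
  identical seeds reproduce event tables bit-exactly.
- **Fokker–Planck solver.** Cell-centered finite volumes with backward-Euler
  time stepping, implicit reinjection of the threshold flux at the reset,
  and a second-order one-sided threshold-flux stencil. Probability is
  conserved to $10^{-10}$ per step; the solver warns when the cell Péclet
  number indicates an under-resolved advection limit.
- **Decoding.** Centroids are intensity-weighted circular means on the
  torus over pixels above a threshold multiple of the mean; phase lags are
  single-frequency Fourier projections with a reliability flag based on the
  response amplitude.

## 6. Limitations

- The Fourier rate solution assumes the analytic Gaussian kernels; the
  sampled networks use the clipped, water-filled kernels, so at strongly
  clipped parameters the prediction matches simulated rate maps only after
  block-averaging (the tests verify block-level correlation and scale).
- Quenched connectivity disorder dominates single-trial spatial rate maps;
  map-level comparisons require trial averaging.
- The `poisson_like` feedforward drive approximates shot noise by Gaussian
  noise with the matching VMR; at very low rates the discreteness of real
  spike input is not captured.
- Finite-size rate suppression is strong at the reduced test scales, so
  simulated rates are compared against `finite_N_rates()`, not the
  large-$N$ limit.
- Phase-lag estimates on single trials are noisy at long periods (slow
  network fluctuations); trend analyses average rate traces over trials
  before estimating a phase.
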