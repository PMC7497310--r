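# einet

Simulation and theory for excitation–inhibition (E–I) balanced spiking
networks of non-leaky linear integrate-and-fire neurons, used as fast
population-level signal detectors. The package bundles:

- a time-stepped spiking simulator for dense random (homogeneous) and
  spatially local (Gaussian-kernel) networks with exponential synapses;
- closed-form mean-field firing rates (large-*N* limit and finite-*N*
  threshold-linear correction) and balance-condition checks;
- the membrane-potential Fokker–Planck density: stationary closed form and a
  conservative finite-volume transient solver;
- a synthetic event-camera ("spike camera") front end that encodes moving
  disc stimuli into pixel spike trains;
- readout tools: population rates, object-centroid decoding, temporal and
  spatial phase lags, pairwise-correlation asynchrony diagnostics;
- a command-line interface (`inst/cli/einet`) with named parameter presets.

## The model

Each neuron integrates its input without leak,

    tau_a dv_i/dt = I_i(t),    spike when v_i >= theta, reset to v0,

so an uncoupled population with mean input `mu` fires at the threshold-linear
rate `r = max(mu, 0) / (theta tau)` regardless of the input variance. In the
recurrent network, population `a` (E or I) receives

    I_a = N [ f_a mu_F + w_aE r_E + w_aI r_I ] / N-scaled synapses,
    w_ab = p_ab j_ab q_b,

with dense connection probabilities `p_ab`, weights `j_ab / N`, and
population fractions `q_b`. When the weight ratios obey the strict balance
ordering

    f_E / f_I  >  |w_EI| / |w_II|  >  w_EE / w_IE,

the large excitatory and inhibitory currents cancel to O(1) per neuron and
the self-consistent rates follow from `theta tau_a r_a = N (f_a mu_F +
sum_b w_ab r_b)`: the large-`N` limit solves the 2×2 linear system, and
`finite_N_rates()` keeps the O(1/N) left-hand side. Because the neurons are
non-leaky, the population rate tracks input changes essentially
instantaneously when the input noise keeps a constant variance-to-mean ratio
(VMR); the membrane-potential density `p(v)` obeys an advection–diffusion
Fokker–Planck equation whose stationary solution is available in closed form
(`fp_stationary_pdf()`).

The spatial variant places E, I, and pixel (F) populations on unit-square
grids, draws connections from Gaussian kernels with widths `A_F > A_E >=
A_I`, and admits a two-dimensional Fourier rate solution
(`fourier_rates()`). A disc stimulus encoded by the pixel layer can then be
decoded from the balanced layer's activity (`track_object()`,
`decode_centroid()`), with tracking quality summarized by centroid RMSE and
temporal/spatial phase lags.

## Worked example

```r
library(einet)

net <- balanced_network(N = 2000, q_I = 0.2, p = 0.25,
                        j = matrix(c(0.25, 0.4, -1, -1), 2, 2),
                        f = c(E = 3, I = 2), theta = 15,
                        tau_m = c(E = 15, I = 10), tau_s = c(E = 6, I = 5))

round(check_balance_condition(net)$ratios, 4)
#>      drive inhibition excitation
#>      1.500      1.000      0.625

round(limit_rates(net, 0.1)$r, 4)       # large-N rates at mu_F = 0.1
#>      E      I
#> 3.3333 9.3333

round(finite_N_rates(net, 0.1)$r, 4)    # finite-N correction at N = 2000
#>      E      I
#> 2.3280 3.0899

sim <- simulate(net, seed = 10,
                drive = feedforward_drive(0.1, vmr_mode = "poisson_like",
                                          beta_F = 0.1),
                duration = 150, dt = 0.05)
tr <- rate_trace(sim, bin = 0.5)
mean(tr$r[tr$t > 30])                   # simulated E rate after the transient
#> [1] 2.2441                            # within 4% of the finite-N theory

fp_stationary_pdf(0, mu = 1, sigma2 = 1)  # stationary density at the reset
#> [1] 0.8646647                           # = 1 - exp(-2)
```

## CLI

```sh
Rscript inst/cli/einet recipe fig3 --scale 0.2 --seed 1 --out runs/fig3
Rscript inst/cli/einet fp stationary --mu 1 --sigma2 1 --out fp.json
Rscript inst/cli/einet predict rates --config config.yaml
```

See `vignette("balanced-networks")` for the model details, numerical choices,
and limitations.
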