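Package: einet
Title: Excitation-Inhibition Balanced Spiking Networks for Fast Signal
    Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and theory for excitation-inhibition (E-I) balanced
    networks of non-leaky linear integrate-and-fire neurons used as fast
    signal detectors.  Provides dense random and spatially local (Gaussian
    kernel) connectivity, a time-stepped spiking simulator with exponential
    synapses, closed-form mean-field firing rates (large-N limit and finite-N
    threshold-linear correction), the membrane-potential Fokker-Planck
    density with its stationary solution and a conservative transient solver,
    a synthetic event-camera front end with disc stimuli, and analysis tools
    for population rates, object-centroid decoding, temporal and spatial
    phase lags, and asynchrony diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
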