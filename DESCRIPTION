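Package: mecgamma
Title: Conductance-Based Simulation and Wavelet Analysis of Theta-Nested
    Gamma Oscillations in the Medial Entorhinal Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a network of 100 fast-spiking parvalbumin-positive
    interneurons and 400 stellate cells of medial entorhinal cortex layer
    II/III under 8 Hz optogenetic-style conductance drive, and analyses the
    resulting synaptic currents and spike trains the way slice
    electrophysiologists do: zero-phase Butterworth band-pass filtering,
    per-theta-cycle analytic Morlet scalograms with artifact and
    signal-quality exclusions, spike phase and interspike-frequency
    histograms. Experiment drivers sweep the excitatory-to-inhibitory
    conductance across connectivity seeds, simulate AMPA blockade, and vary
    the GABA-A reversal potential to map the transition between
    interneuron-network gamma (ING) and pyramidal-interneuron network gamma
    (PING) regimes. Includes a seeded synthetic-signal generator for
    ground-truth testing of every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    stats,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
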