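Package: dynsyn
Title: Dynamic Stochastic Synapses with Bin-Level Spike-Timing-Dependent Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a fully connected two-neuron network of dynamic stochastic
    synapses in which short-term plasticity (facilitation and vesicle-depletion
    release kernels), a homeostatic threshold rule, and a bin-level
    spike-timing-dependent plasticity (STDP) weight update jointly stabilize
    synaptic weights without weight bounds. Provides the release-probability
    kernels, the two-neuron network engine driven by median-thresholded Poisson
    input, seven-cell bin statistics, the STDP learning pass with quiescence
    gating and median-referenced potentiation, experiment drivers (stabilization
    detection, post-stabilization medians, segment slopes, rate sweeps), tidy
    accessors, plotting helpers, and CSV/JSON result serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
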