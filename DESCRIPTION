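Package: eapdemix
Title: Demixing Extracellular Action Potential Sources for Neuron-Type
    Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates spatiotemporal extracellular action potentials (EAPs)
    on high-density linear probes with a line-source forward model over
    simplified labeled morphologies, and demixes the underlying EAP sources
    with multiresolution Haar wavelet features followed by non-negative
    canonical polyadic (CP) tensor decomposition fitted by block coordinate
    descent. Includes the full analysis pipeline around the demixed sources:
    center-channel selection and canonical-waveform gating, restart-similarity
    rank selection, random-forest classification with Gini importances,
    baseline single- and multi-channel waveform features, bootstrapped
    canonical correlation against morphometrics, prevalence-distance scaling,
    an excitatory/inhibitory clustering benchmark, and a bootstrapped
    morpho-electrophysiological (ME) type hierarchy with leave-one-out
    exclusion analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tidyr,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    ranger,
    mclust,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
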