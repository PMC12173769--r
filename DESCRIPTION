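Package: amyfear
Title: Firing-Rate Model of Amygdala Circuitry in Fear Conditioning Under Alcohol
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a five-population firing-rate model of the amygdala
    (lateral amygdala, basal fear and extinction neurons, central amygdala
    pro-fear and pro-extinction neurons) with prediction-error-driven
    synaptic plasticity of its thalamic, hippocampal and infralimbic inputs.
    Runs fear acquisition/extinction protocols under naive, acute-alcohol
    and chronic-alcohol parameter sets, computes trials-to-criterion
    ensemble statistics, and provides phase-plane analysis of the reduced
    central-amygdala subsystem underlying extinction robustness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
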