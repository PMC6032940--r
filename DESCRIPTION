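Package: debipm
Title: Dynamic Energy Budget Integral Projection Models in Stochastic
    Environments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Size-structured demographic projection for the bulb mite
    (Rhizoglyphus robini) using an integral projection model whose vital
    rates derive from dynamic energy budget theory: von Bertalanffy
    growth, feeding-level-dependent maturation and fecundity, and
    starvation-dependent survival.  Builds daily projection kernels over
    a discretized body-length domain, simulates populations through
    coloured (blue/white/red) food time series built by spectral mimicry
    and through two-state Markov chain environments, applies
    size-selective constant-effort harvesting, and computes the long-run
    stochastic population growth rate, its elasticities to life-history
    parameters, and stratified BCa bootstrap confidence intervals for
    comparing predictions with census data.  Includes a generator for
    synthetic census tables that emulate the structure of laboratory
    harvesting experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    boot,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
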