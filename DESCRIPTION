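Package: stnsat
Title: Subthalamic Control of Decision and Movement Speed
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for studying how subthalamic
    nucleus (STN) activity and timed deep-brain-stimulation bursts shape
    decision speed and movement speed in a speed-accuracy trade-off task.
    Provides an end-to-end synthetic experiment generator (drift-diffusion
    behavior, grip-force traces, subthalamic local field potentials, ramped
    stimulation burst schedules), hierarchical Bayesian regression models of
    behavior, a from-scratch hierarchical Bayesian drift-diffusion model with
    trial-level regressors built on the Wiener first-passage-time likelihood,
    a Morlet wavelet time-frequency pipeline with single-trial band-power
    features, and timing-resolved sliding-window cluster-permutation analysis
    of burst stimulation including artifact removal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    rjags,
    coda,
    signal,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    utils,
    ggplot2,
    generics,
    jsonlite,
    arrow,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
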