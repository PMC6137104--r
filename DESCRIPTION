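Package: tandemfret
Title: Hybrid FRET and Simulation Analysis of Multidomain Protein Conformational Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resolving limiting conformational states and submillisecond
    dynamics of multidomain proteins by combining ensemble time-correlated single
    photon counting (TCSPC), single-molecule multiparameter fluorescence detection
    (MFD) burst analysis, and conformational-landscape analysis of replica-exchange
    trajectories. Provides Poisson maximum-likelihood global fitting of fluorescence
    decays with Gaussian-distributed FRET states, static and dynamic FRET lines with
    time-window photon distribution analysis, accessible-volume dye modeling with
    kappa-squared uncertainty from wobbling-in-cone anisotropy, WHAM free-energy
    surfaces with native-contact (Q-value) and buried-surface analysis, and
    exponential fitting of disulfide-formation kinetics. A synthetic-data module
    generates every input the pipeline consumes so all stages are testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    bio3d,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
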