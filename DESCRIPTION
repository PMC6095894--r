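Package: sizecontrol
Title: Cell-Size Homeostasis from Single-Cell Growth Trajectories
Version: 0.1.0
Authors@R: person("sizecontrol", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify cell-size homeostasis from single-cell growth
    data: a stochastic simulator of growing and dividing lineages (linear-response
    and sizer/adder/timer archetypes, G1/S-G2 phase structure, division
    asymmetry), processing of single-cell volume time series (despiking,
    smoothing, Theil-Sen instantaneous growth speed, cell-cycle event windows,
    G1/S detection from a cycle reporter), count-weighted binned regression, and
    estimation of the homeostatic exponent lambda together with its
    decomposition into cell-cycle-timing (theta) and growth-rate (gamma)
    modulation. Also includes fluorescence-exclusion (FXm) volume extraction
    from chamber images and microchannel length-based volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
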