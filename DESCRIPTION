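Package: coenocycle
Title: Simulation and Flow-Cytometry Analysis of Coenocytic Nuclear
    Division Cycles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative analysis of coenocytic cell cycles
    such as that of the ichthyosporean Sphaeroforma arctica, in which
    synchronized nuclear divisions proceed inside a growing multinucleate
    cell before cellularization and burst. Provides a stochastic simulator
    of timer-driven nuclear division (i.i.d. normal division intervals with
    configurable mean and coefficient of variation), flow-cytometry DNA
    content statistics (lowest-peak calibration, discrete power-of-two
    ploidy binning, log2 geometric mean, geometric-standard-deviation
    asynchrony, doubling-time regression, and comparison of observed
    asynchrony against simulated envelopes), cell-size analytics (sphere
    volumes, nuclei-to-volume ratios, relative areas, exact Wilcoxon
    rank-sum comparisons), and a synthetic-data generator that emulates the
    full experiment with known ground truth so every analysis stage runs
    without external data.
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
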