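Package: fepsp
Title: Pharmacological Dissection of Evoked Field Potentials in Brain Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing optic-tract-evoked field excitatory
    post-synaptic potentials (fEPSPs) recorded in superior colliculus slices
    under sequential GABA- and NMDA-receptor blockade. Provides feature
    extraction from averaged sweeps (peak amplitude, latency to peak,
    duration, late-phase area under the curve), per-slice GABA- and
    NMDA-receptor contribution indices computed from drug-condition AUC
    differences, group-level inference (paired t-tests, one-way ANOVA with
    Tukey HSD, including a summary-statistics route for working from
    published mean/SEM tables), and a calibrated synthetic sweep generator
    that emulates the recording protocol for testing and power analysis.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
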