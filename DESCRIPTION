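Package: coraloptics
Title: Skeletal Optics, Photophysiology and Bleaching Dynamics of Coral Holobionts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing optical-feedback dynamics in coral bleaching.
    Implements an empirical two-pass model of light absorption by in-hospite
    Symbiodinium that partitions absorbed light into a first (downwelling) pass
    and a skeleton-dependent reflected pass inferred from holobiont and bare
    skeleton reflectance; PAM chlorophyll-fluorometry metrics (dark-adapted
    yield, steady-state quantum-yield partitioning, maximum excitation pressure
    over PSII); white-standard reflectance normalisation and replicate
    aggregation; Taylor-expansion isolation of light- and temperature-dependent
    bleaching rates with clustered longitudinal inference; and a seeded
    synthetic-experiment generator emulating a ten-species, four-treatment
    repeated-measures heat and light stress design for end-to-end parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    lme4,
    lmerTest,
    sandwich,
    lmtest,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
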