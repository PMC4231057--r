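Package: bbbflux
Title: Transwell Permeability, TEER and Radiation-Injury Assay Analysis for
    Blood-Brain Barrier Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of in vitro and in vivo
    blood-brain barrier integrity assays. Estimates endothelial permeability
    coefficients (Pe) from transwell tracer flux using cleared-volume
    regression and series-conductance correction for the cell-free insert,
    normalizes transendothelial electrical resistance (TEER) readings,
    quantifies Evans blue extravasation in brain tissue through a linear
    standard curve, summarizes count-based cellular endpoints (endothelial
    progenitor colonies, senescence fractions, cell densities, stained-area
    image intensity), and provides dose-by-time ANOVA with Bonferroni
    post-tests against sham. A forward simulator of every assay, with
    configurable kinetic parameters, effect structure and noise, supports
    validation and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    car,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
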