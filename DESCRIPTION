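Package: rhizodyn
Title: Fine-Root Demography, Phenology, Interval-Censored Survival and
    Tree Biophysics from Minirhizotron Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative machinery for soil-temperature by root-dynamics
    experiments on tree seedlings observed through minirhizotron imaging.
    Provides standing-length, elongation and mortality statistics per unit
    image area; threshold-based detection of root and shoot growth
    initiation, cessation and peak rates, and the root-shoot offset;
    nonparametric maximum-likelihood estimation (Turnbull) of the survival
    function from interval-censored root lifetimes, with a permutation
    k-sample logrank test using Sun-type scores, bootstrap confidence
    intervals and fine-root turnover estimates; subspace (CLAFIC)
    classification of electrical impedance spectra; closed-form static
    chamber gas-flux and hydraulic-conductance temperature-correction
    computations; and a synthetic-data generator with known ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
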