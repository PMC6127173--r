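Package: angiotrial
Title: In Silico Anti-Angiogenic Mouse Trials with VEGF-Coupled Tumour
    Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mechanistic simulation and analysis of randomized in silico
    mouse trials of anti-VEGF therapy. A three-compartment mass-action
    model of VEGF isoform transport, receptor binding and bevacizumab
    neutralization drives a switching (exponential-to-linear) tumour
    growth law through a pro-angiogenic signal. The package generates
    virtual tumour-bearing mouse populations with heterogeneous growth
    kinetics, applies trigger-started dosing protocols, derives survival
    records from a sacrifice rule, performs Kaplan-Meier, log-rank and
    Mantel-Haenszel hazard-ratio analyses, and sweeps tumour growth
    kinetic parameters (the k0/k1 ratio and k1) for threshold values
    that stratify population survival. Includes bounded multistart
    least-squares fitting of growth kinetics to tumour volume data and
    synthetic data generators for all pipeline inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    survival,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
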