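Package: xenofate
Title: Discovery and Annotation of Xenobiotics and Their Biotransformation
    Products in Untargeted LC-MS Metabolomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An untargeted ADME/TK workflow for LC-MS metabolomics peak
    matrices. Discovers putative xenobiotic-related features with three
    intensity-based filters (exposed presence, control presence, fold
    change), groups them into compound groups by adduct/isotope ion-form
    relations at ppm/retention-time tolerances, annotates groups against
    rule-based Phase I/II biotransformation predictions from the parent
    molecular formula, corroborates annotations with MS2 fragment-shift
    alignment against the parent spectrum, analyses temporal and
    dose-response behaviour (k-means profile clustering, ANOVA/Tukey,
    Spearman correlation networks), and returns a cleaned endogenous
    matrix (blank/QC/missingness filters, PQN, kNN imputation, glog, PCA,
    t-tests, Fisher over-representation analysis). Includes a synthetic
    data generator with ground truth so the full pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
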