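Package: faimscv
Title: Compensation-Voltage Prediction and SEC-Aware FAIMS Scheduling for Cross-Linked Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing field asymmetric waveform ion-mobility
    (FAIMS) separations of cross-linked peptides. Reads and filters
    cross-link spectrum match (CSM) tables, computes physicochemical
    feature vectors for cross-linked peptide pairs, trains and explains a
    gradient-boosted regression of the FAIMS compensation voltage (CV),
    and optimises two-CV acquisition schedules per size-exclusion
    chromatography (SEC) fraction by exhaustive pairwise combination of
    unique residue pair yields. Ships a seeded synthetic-data generator
    that emulates tryptic cross-linked analytes, mass-coupled SEC
    fractionation and Gaussian CV transmission for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
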