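Package: albench
Title: Active-Learning Benchmarks for Ligand Binding-Affinity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for benchmarking batch-mode active learning
    on compound potency data. Provides a Gaussian-process surrogate with a
    Tanimoto kernel over binary molecular fingerprints, random, exploration
    (maximum predictive variance) and exploitation (maximum predicted potency)
    acquisition strategies, a catalogue of fixed-budget acquisition protocols,
    top-k recall and F1 enrichment metrics alongside standard regression
    metrics, a Gaussian label-noise robustness experiment, and a synthetic
    structure-activity library generator that emulates congeneric,
    heterogeneous and small diverse compound pools. Circular (Morgan-style)
    hashed fingerprints can be computed from SMILES via OpenBabel-based
    parsing, and pools can be read from and written to plain CSV.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
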