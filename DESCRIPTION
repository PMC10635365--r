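Package: dacsaug
Title: Drug Synergy Dataset Augmentation by Action/Chemical Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Expands drug-combination synergy datasets by substituting
    pharmacologically equivalent compounds. Drug-drug similarity is
    quantified three ways (Kendall tau-b rank correlation of monotherapy
    pIC50 profiles across shared cancer cell lines, Matthews correlation
    of protein-target sets over a fixed protein universe, and Tanimoto
    similarity of path-based molecular fingerprints) and combined into
    the DACS score. Pairs whose DACS similarity exceeds a data-driven
    cutoff donate substitute compounds that inherit the parent
    combination's cell line and synergy score. The benefit of the
    augmented dataset is measured with leakage-aware random-split and
    tissue-based cross-validation of random forest and gradient boosted
    tree classifiers. Includes a synthetic cohort generator so the whole
    pipeline runs without external downloads, plus readers and writers
    for the tabular input formats and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ranger,
    xgboost,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
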