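Package: xtalprop
Title: Protein Crystallization Propensity Prediction from Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the propensity of protein targets to pass the five
    consecutive steps of a structural-genomics crystallization pipeline
    (cloning, material production, purification, crystallization, and
    diffraction-quality crystal yield) from sequence alone. Encodes each
    protein into a fixed 2,924-feature candidate set (AAindex physicochemical
    averages over the whole sequence and over predicted exposed/buried
    residues, PROFEAT-style descriptors, and sequence/structure summary
    features), selects features by one-step or two-step minimum-redundancy
    maximum-relevance ranking followed by incremental or forward wrapper
    selection under cross-validated AUC, trains two-level stacked
    probability-output support vector machines, and maps the resulting
    crystallizability scores onto five difficulty tiers for target triage.
    Includes dataset construction from experimental status records,
    CD-HIT-style redundancy reduction, synthetic-data generators, and a full
    evaluation toolkit (ROC/AUC, MCC, cross-validation, feature
    significance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
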