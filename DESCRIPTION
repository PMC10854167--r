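Package: methorigin
Title: Tissue-of-Origin Classification from Targeted DNA Methylation Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds compact CpG methylation panels for predicting the tissue
    of origin of tumours, including those of unknown primary. Implements the
    full pipeline: per-CpG one-way ANOVA with Tukey HSD post hoc and a
    delta-beta effect-size filter; two-step random-forest feature selection
    driven by out-of-bag permutation importance and OOB-error-guided forward
    inclusion, with multi-run union and top-K panel extraction; multinomial
    random-forest, lasso and elastic-net classifiers with per-class
    probabilities; confusion-matrix and sensitivity/specificity/PPV/NPV
    reporting; quantification of targeted bisulfite sequencing counts
    (Bismark coverage format) into classifier-ready beta values; CpG
    island/shore/shelf and gene-region annotation of panel probes; and a
    seeded synthetic-cohort generator so every stage is testable without
    external array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    optparse,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
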