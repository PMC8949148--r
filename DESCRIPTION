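Package: amenability
Title: Multi-Label Prediction of GC- and LC-HRMS Amenability from Molecular Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether a chemical is amenable to gas
    chromatography, reversed-phase liquid chromatography (both coupled to
    high-resolution mass spectrometry), or both, from tables of numeric
    molecular descriptors. Provides an expert rule-based baseline built on
    boiling point, molecular weight and logP; a six-stage feature-selection
    pipeline (quasi-constant filter, Spearman correlation filter, random-forest
    importance filter, recursive feature elimination with cross-validation,
    repeated sequential forward selection, and overlap-based consensus); a
    multi-output decision tree with grid search and depth selection; the
    label-based (Hamming) accuracy and full multi-label classification report;
    and the nonparametric machinery to compare classifiers (Friedman test with
    Kendall's W, Nemenyi post hoc, one-sided Wilcoxon signed-rank with
    matched-pairs rank-biserial correlation and common-language effect size,
    McNemar test with odds ratio). A synthetic descriptor generator with
    planted informative, redundant, quasi-constant and noise columns makes the
    whole workflow testable end to end.
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
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
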