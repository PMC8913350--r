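Package: lipidheart
Title: Lipid-Class Fold-Change Statistics and Cardiac Phenotyping for
    Mouse Lipidomics Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for the computational analysis of a
    choline kinase beta (Chkb) deficiency cardiac study in mouse: cleanup of
    LipidSearch-style lipidomics peak tables (signal-to-noise and peak-quality
    filtering, a triplicate-exclusion rule, adduct aggregation, replicate
    averaging), class-level paired fold-change statistics using an exact
    Wilcoxon signed-rank test with Bonferroni family-wise control and dual
    pre/post-correction reporting, echocardiography-derived cardiac function
    indices (stroke volume, ejection fraction, fractional shortening, cardiac
    output, corrected left-ventricular mass, hypertrophy index) with one-way
    ANOVA and Tukey HSD group comparison, stereological point-count estimators
    and delta-delta-Ct relative expression, and a synthetic-data module that
    emulates every pipeline input so the full analysis is testable end to end.
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
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    broom,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
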