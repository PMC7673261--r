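Package: orthocat
Title: Cross-Species Cell-Type Homology by Correspondence-at-the-Top of
    Ranked Marker Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maps homologous sorted cell populations between two species from
    bulk RNA-seq compendia. Counts are restricted to autosomal one-to-one
    orthologs, variance-stabilized, subject-regressed with per-gene
    random-intercept mixed models, and quantile-normalized across species.
    Subtype-specific marker genes are ranked by the product of the
    median-scaled expression and a Stouffer-combined Z over all pairwise
    subtype contrasts, gated by a Benjamini-Hochberg-adjusted overall F-test.
    Cross-species homologs are assigned by the mean correspondence-at-the-top
    (CAT) overlap of the ranked marker lists over list sizes 1 to L. Includes
    earth-mover's-distance times ROC-AUC scoring of external signature gene
    sets and a synthetic two-species cohort generator with planted marker
    programs for end-to-end validation.
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
    limma,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    DESeq2,
    lme4,
    lmerTest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
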