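Package: protmr
Title: Proteome-Wide Bidirectional Mendelian Randomization at Desk Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for bidirectional proteome-wide Mendelian
    randomization (MR) from GWAS summary statistics: cis/trans pQTL
    instrument construction with LD clumping and proxy substitution,
    inverse-variance-weighted, Egger, weighted-median and weighted-mode
    estimators, pleiotropy sensitivity analyses (residual-sum-of-squares
    outlier simulation, HEIDI-style filtering, multivariable MR on
    z-scores), multiplicity control and replication, a phenome-wide scan
    with hypergeometric over-representation testing, multi-trait Bayesian
    colocalization from approximate Bayes factors, and single-cell
    pseudobulk cell-type enrichment and differential expression.  A
    synthetic summary-statistics and single-cell generator provides
    ground-truth causal structures so every stage can be exercised and
    calibrated without biobank-scale data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    graphics,
    Matrix,
    limma,
    edgeR,
    yaml
Suggests: testthat (>= 3.0.0), optparse, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
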