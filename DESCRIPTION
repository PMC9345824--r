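Package: crosstraitr
Title: Genome-Wide Cross-Trait Analysis from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the shared genetic architecture of two
    complex traits from genome-wide association study (GWAS) summary
    statistics alone. Implements LD-score regression for SNP heritability
    and overall genetic correlation with block-jackknife uncertainty,
    local genetic covariance and correlation over LD-independent regions
    via truncated eigendecomposition of regional LD, cross-phenotype
    association meta-analysis (homogeneous and heterogeneous-effects
    statistics) with pleiotropic-SNP screening, greedy LD clumping and
    locus classification, transcriptome-wide association from precomputed
    expression weights with per-tissue false discovery rate control, and a
    bidirectional two-sample Mendelian randomisation suite (inverse
    variance weighted, MR-Egger with SIMEX correction, weighted median,
    Cochran's Q, MR-PRESSO, Steiger filtering, leave-one-out, instrument
    strength and power analysis). A synthetic-data module generates
    coupled summary statistics, LD panels, instrument sets and expression
    weights with known ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
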