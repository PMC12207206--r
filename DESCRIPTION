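Package: icirwe
Title: Real-World Characterization of Immune-Checkpoint-Inhibitor Resistance in NSCLC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis machinery for characterizing primary versus acquired
    resistance to immune checkpoint inhibitors (ICI) from multimodal
    real-world non-small cell lung cancer data. Provides rule-based
    treatment-timeline phenotyping of post-ICI biopsies, derivation of
    real-world overall survival and progression-free survival endpoints,
    Cohen's-kappa-optimal imputation of PD-L1 IHC class from CD274 mRNA,
    TMM/log-CPM normalization and gene-signature scoring, covariate-adjusted
    differential expression with preranked gene-set enrichment, a per-gene
    Cox survival screen with cross-cohort intersection, single-cell
    pseudobulk projection of hit genes onto cell types, and a seeded
    synthetic-cohort generator that emulates the structure of the clinical
    and expression data so the whole pipeline can be exercised end to end
    without access to licensed patient-level data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    emmeans,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
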