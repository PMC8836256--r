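Package: evmir
Title: Serum Extracellular-Vesicle miRNome Analysis with Stage-Specific
    Biomarker Discovery
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of serum extracellular-vesicle (EV)
    microRNA UMI count matrices: background-noise filtering,
    Spearman-based outlier subject exclusion, trimmed-mean-of-M-values
    (TMM) normalization, negative-binomial differential expression with
    quasi-likelihood F-tests and an exact conditional test,
    disease-stage-specific miRNA set calling by double dissociation,
    z-scored ROC biomarker panel construction with a greedy stop rule,
    hypergeometric pathway over-representation of validated miRNA
    targets, matched serum-CSF compartment comparison with a
    two-population split, and RT-qPCR Delta-Cq validation.  Ships a
    negative-binomial synthetic-data generator with planted ground truth
    emulating a five-group case-control study design, so every stage is
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    limma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
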