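Package: isomiRpipe
Title: IsomiR Classification, Differential Expression and Regulatory
    Circuit Assembly for Small RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies adapter-trimmed small RNA-seq reads against a
    miRBase-like reference of precursor hairpins and mature arms into
    reference miRs and isomiR classes (templated 5'/3'/5'3' end variants
    and non-templated 3'-tailed variants) with an explicit end-offset
    nomenclature, quantifies them into count matrices, tests two-group
    contrasts with a negative-binomial Wald test, and integrates
    differentially expressed miRs/isomiRs with differentially expressed
    mRNAs and literature-curated TF-miR regulations into sign-correlated
    target pairs and a TF-miR/isomiR-gene regulatory circuit. Includes a
    seeded synthetic-data generator emitting ground-truth tables so every
    stage is testable end to end, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    rtracklayer,
    BiocGenerics,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Sequencing, SmallRNA, DifferentialExpression, NetworkInference
RoxygenNote: 7.3.3
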