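Package: xembryo
Title: Cross-Species Preimplantation Embryo scRNA-seq Analysis with
    Annotation Reconciliation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing preimplantation-embryo single-cell
    RNA-seq data across species. Implements rule-based repair of an
    incomplete genome annotation from assembled transfrags
    (gffcompare-style class-code classification, filtering and locus
    reassignment), cell- and gene-level quality control,
    log-normalization, variable-gene ranking and covariate-regressed
    scaling, Wilcoxon rank-sum marker and differential-expression
    calling with Bonferroni correction, pseudo-bulk averaging,
    one-to-one ortholog alignment, lineage-conservation classification
    across species, and mutual-nearest-neighbour pairing for
    developmental-stage alignment. A synthetic-data module generates
    annotation and count-matrix fixtures with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
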