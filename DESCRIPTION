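Package: mousecgp
Title: Genomic Credentialing of Mouse Tumor Models from Targeted Amplicon Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Toolkit for genomic credentialing of genetically engineered mouse
    tumor models profiled with targeted multiplex-PCR (amplicon) panels.
    Implements amplicon read-count normalization against a pooled normal with
    GC loess correction, gene-level copy-number calling with false discovery
    control, circular-binary-segmentation-style profile segmentation,
    coverage-restricted chromosome-arm aneuploidy calling (the R_c metric with
    a gene directionality filter), supervised mouse strain-admixture
    estimation from small SNP sets selected by multiple correspondence
    analysis, cross-species amino-acid hotspot mapping by windowed protein
    alignment, and credentialing statistics: fraction of genes altered,
    copy-state scores, flox-site ratio analyses, Fisher exact tests,
    within-sample permutation tests for recurrent aneuploidy, and
    synteny-aware cross-species scenario tests. Synthetic-data generators
    with known ground truth make the full pipeline testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
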