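Package: meatqtl
Title: Expression and Splicing QTL Mapping for Meat-Quality Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Association mapping of gene expression (eQTL) and exon usage
    (sQTL) against SNP genotypes in muscle transcriptome studies of meat
    quality. Provides a composite meat-quality index built from carcass and
    sensory traits by principal components, Huber M-estimator robust
    regression to call genes whose expression explains index variation,
    TMM and median-of-ratios count normalization with a closed-form
    negative-binomial variance stabilizing transformation, a covariate-
    adjusted linear-model scan over all SNP-feature pairs with cis/trans
    classification, simpleM effective-number-of-tests multiple testing
    correction, trans-hotspot and master-regulator detection, and a
    self-consistent synthetic data generator with planted effects for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    MASS,
    edgeR,
    withr,
    optparse
Config/testthat/edition: 3
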