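Package: dimorphseq
Title: Sexually Dimorphic Gene Expression Across Mouse Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for analysing sexually dimorphic gene
    expression across mouse development from bulk and low-input RNA-seq
    count matrices. Provides sex calling of samples from Xist and Eif2s3y
    marker expression, negative-binomial two-group testing with
    median-of-ratios normalisation and Benjamini-Hochberg correction to
    define dimorphism signatures, projection of a fixed signature onto
    other developmental stages with directional-consistency and
    correlation statistics, an X-chromosome dosage-correction model for
    sex-comparative ChIP-seq TSS enrichment with permutation tests,
    gene-set overlap and hypergeometric pathway enrichment with custom
    backgrounds, and a synthetic-data generator that emulates the
    statistical structure of such studies with ground-truth labels for
    recovery and calibration testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
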