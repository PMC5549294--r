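Package: enhancerscan
Title: Random-Forest Enhancer Discovery from Chromatin-Mark Coverage Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts enhancer elements genome-wide from chromatin
    accessibility (DNase-seq) and histone-mark (H3K4me1, H3K27ac, H3K4me3)
    coverage tracks. A random forest is trained on known enhancer elements
    against promoter regions, applied to 200-bp genome windows, and the
    resulting enhancer windows are merged and validated against DNase
    hypersensitive site peaks. Validated enhancers are stratified into
    active and primed states by H3K27ac level and annotated with
    bidirectional eRNA coverage from GRO-seq strand tracks. Also provides
    the surrounding signal math (1x RPGC normalization, effective genome
    size, strand cross-correlation fragment-length estimation), expression
    integration (FPKM/TPM near peaks, promoter-proximal co-occupancy), a
    deterministic synthetic-data simulator for benchmarking every stage,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
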