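Package: xdose
Title: Dosage Compensation and Meiotic Sex Chromosome Inactivation Analysis for X0/XX Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chromosome-level analysis of X-linked gene expression in species
    with XX/X0 sex determination. Identifies the X chromosome from male versus
    female DNA-seq coverage, filters and normalizes RNA-seq count matrices
    (TMM/CPM/RPKM), computes per-gene log2 male:female expression ratios and
    X-versus-autosome rank statistics, tests for expression reduction beyond
    the hemizygous two-fold expectation (meiotic sex chromosome inactivation),
    computes the Tau tissue-specificity index, profiles ChIP/input enrichment
    in genomic windows, and estimates the germline fraction of gonad samples
    under a germ/soma mixture model. Includes a negative-binomial synthetic
    study generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    edgeR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
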