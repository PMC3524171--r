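Package: StarchSAGE
Title: DeepSAGE Tag Profiling and Starch-Metabolism Analysis for Potato Tubers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for DeepSAGE (deep serial analysis of gene expression)
    digital expression profiling of potato tuber starch metabolism: key-based
    demultiplexing of pooled amplicon reads, NlaIII (CATG)-anchored 21-bp tag
    extraction, tag-to-gene annotation through a virtual-tag index built from a
    transcript collection, tags-per-2,000,000 normalization, pooling of
    biological replicates, aggregation of gene counts to metabolic steps, PCA
    replicate quality control and cross-cultivar differential expression by
    Student's t-test. Companion biochemistry tools compute phosphoglucomutase
    activities from A340 absorbance traces, quantify sucrose and hexose
    phosphates from chromatogram peak areas via linear standard curves, form
    per-chromatogram G1P/G6P ratios, and evaluate the thermodynamic equilibrium
    of the phosphoglucomutase reaction. A synthetic-data module generates every
    input the pipeline consumes, with truth tables, so the whole analysis is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
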