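Package: cernaflow
Title: Competing Endogenous RNA Network Inference from Two-Group Whole-Transcriptome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a two-breed skin whole-transcriptome
    analysis workflow: negative-binomial differential expression with
    Benjamini-Hochberg correction, miRNA-target prediction intersection with
    negative co-expression filtering, shared-miRNA hypergeometric ceRNA pair
    and sponge-miRNA-mRNA triplet inference, back-splice circRNA junction
    calling from clipped SAM alignments, and small assay computations
    (2^-ddCt relative expression, melanin working curve, follicle density).
    A synthetic-data generator with planted ground truth drives every stage,
    so the whole pipeline is testable without any sequencing download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
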