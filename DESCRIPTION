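Package: piragut
Title: piRNA Discovery and Regulatory-Network Analysis from Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for PIWI-interacting RNA (piRNA) analysis
    in insect small RNA-seq data: collapsed-read import, exact k-mer genome
    mapping, annotation-cascade filtering of rRNA/tRNA/snRNA/snoRNA/scRNA/miRNA
    contaminants, piRNA candidate calling by length window (24-33 nt) and the
    unique-position rule, length-distribution and first-base-bias statistics,
    tags-per-million (TPM) normalization, fold-change plus t-test differential
    expression screening, mismatch-bounded antisense target scanning with
    nearest-neighbor RNA duplex free-energy filtering, Fisher-exact term
    enrichment with rich factors, and bipartite piRNA-mRNA regulatory network
    construction. Includes a fully seeded synthetic-data generator that plants
    ground-truth piRNA loci, contaminants, fold changes and target sites for
    validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
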