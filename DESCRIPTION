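Package: lariatscan
Title: Genome-Wide Mapping of Intron Lariats and Branch Points from RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds exhaustive intron-lariat signature databases (canonical and
    exon-skipping) from a genome and annotation, maps RNA-seq reads that fail
    genome/transcriptome alignment onto those signatures with a mismatch-tolerant
    ungapped matcher, and calls intronic branch points genome-wide with a
    clustering scheme robust to reverse-transcriptase errors. Also computes
    per-intron splicing efficiency from diagnostic exon-exon junction and
    exon-intron boundary reads, tests differential splicing across replicated
    conditions with the Cochran-Mantel-Haenszel test, and estimates false
    discovery rates. Includes a synthetic-data generator producing genomes,
    annotations and strand-specific reads (mRNA, pre-mRNA and lariat-junction
    reads with configurable branch-point mutation) together with ground truth,
    so the whole workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
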