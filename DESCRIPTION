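Package: panproject
Title: Founder-Sequence Pangenome Alignment Projection and Reference-Bias
    Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds founder sequences from a phased variant panel so that
    every panel haplotype is a recombination (mosaic) of few founders,
    projects read alignments from founder coordinates back to the linear
    reference through a reference-guided multiple sequence alignment
    (rewriting CIGAR edit scripts in linear time), recalculates mapping
    qualities over partitions of alignments sharing a projected leftmost
    coordinate, and evaluates reference bias via per-site allele balance
    and alignment precision/recall. Includes a deterministic synthetic-data
    generator (reference, phased panel, held-out diploid donor, error-bearing
    reads with truth positions) so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    jsonlite,
    methods,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
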