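Package: hgtbench
Title: Simulate Horizontal Gene Transfer in Microbial Communities and
    Benchmark Its Recovery from Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Plants user-defined horizontal gene transfer (HGT) events into
    recipient genomes and evaluates whether they can be recovered from
    metagenomic assemblies. Donor genes are diverged with a codon-structured
    mutation model that partitions changes into silent and non-silent
    one-, two- and three-base codon mutations, preserving reading frames
    and avoiding start/stop codons. Mutated genes are flanked, inserted at
    random or intergenic breakpoints of recipient genomes with a replayable
    insertion report, and an error-free paired-end read simulator produces
    community sequencing data at user-defined abundances. A recovery
    evaluator scores planted transfers against assembled contigs using
    identity, coverage and flanking-context criteria. A fixture generator
    builds synthetic donors, recipients, annotations and perfect contigs so
    the whole pipeline runs without external data or aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
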