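Package: caninakit
Title: Canina Meiosis Modelling and Pentaploid Dogrose Genome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the asymmetric (Canina) meiosis of pentaploid
    dogroses (Rosa sect. Caninae, 2n = 5x = 35) and its genomic signatures.
    Implements the inheritance model (7-chromosome haploid pollen, 28-chromosome
    tetraploid egg, seed-tissue ploidy ratios, hybrid subgenome dosage),
    identification of the bivalent-forming subgenome from pollen single-copy
    orthologue (SCO) mappings, read-coverage based subgenome dosage inference in
    synthetic hybrids, functional centromere annotation from CENH3/H3 ChIP
    enrichment with satellite/retrotransposon composition classification, and
    LTR retrotransposon insertion-time dating under the Jukes-Cantor model.
    A seeded synthetic pentaploid genome generator (FASTA/GFF3/BED/FASTQ/
    bedGraph bundles with ground truth) makes every analysis testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
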