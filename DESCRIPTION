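Package: paraquant
Title: Copy-Number-Annotated Read Collapsing and Paralog-Aware
    Expression Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Losslessly collapses high-throughput sequencing read files
    into a deduplicated FASTA+/FASTQ+ representation in which each
    distinct sequence is stored once under a SeqID_CopyNumber
    identifier with per-site averaged Phred quality scores, and
    quantifies gene expression with a paralog-aware allocation of
    multi-mapping reads: shared reads are divided among members of a
    paralogous gene family in proportion to unique-match evidence,
    resolved progressively from pairwise-shared up to family-wide
    shared read sets, with alternative bit-score- and e-value-weighted
    schemes.  Includes an exact k-mer seeded ungapped read matcher, a
    BLAST-tabular hit importer, Count / Count-per-Kb / FPKM reporting,
    and a seeded synthetic read simulator with ground truth for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'allocation.R'
    'cli.R'
    'dedup.R'
    'matcher.R'
    'paraquant-package.R'
    'quantify.R'
    'seqformats.R'
    'synthetic.R'
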