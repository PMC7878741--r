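Package: telocatr
Title: Positional Annotation of Transposable Elements at Transcript Ends
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies where annotated repeat elements (in particular Alu
    retrotransposons such as AluYRa1) sit relative to gene transcript
    structure: 5'UTR start, ORF boundaries, exon splicing junctions, UTR
    interiors and the 3'UTR terminus, in sense or antisense orientation.
    Maps genomic positions into repeat consensus coordinates to resolve the
    Alu anatomy (left arm, A-rich linker, right arm, poly-A tail), joins
    TAPAS-format alternative-polyadenylation calls onto located elements,
    scans for polyadenylation signal hexamers and the CA cleavage
    dinucleotide, and ships a seeded synthetic-fixture generator with
    planted ground truth plus a brute-force per-base classification oracle.
    Readers and writers cover the UCSC genePred/refGene, refFlat and
    RepeatMasker (rmsk) table dialects and the six-column TAPAS output.
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
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
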