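Package: intronDecay
Title: Identification of Exosome-Targeted Transcripts and Decay-Promoting
    Introns from CRAC and RNA-Seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to identify direct RNA targets of the fission-yeast
    exosome specificity factor Mmi1 and to call decay-promoting introns.
    Implements CRAC (UV cross-linking and analysis of cDNA) read-cluster
    calling and hexamer enrichment against mononucleotide-shuffled
    backgrounds, abundance-normalised binding enrichment with pA+/pA-
    classification, a negative-binomial Wald test for wild-type versus
    deletion-mutant RNA-seq, intron-retention metrics (5' splice-site
    boundary reads per million and intron/exon FPKM ratios), transcription
    readthrough classification downstream of annotated 3' ends, and a
    combined caller that integrates intronic binding, TNAAAC motif content
    and precursor stabilisation.  A synthetic-data module generates a toy
    genome, annotation, truth set and simulated CRAC and RNA-seq libraries
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    Rsamtools,
    GenomicAlignments,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
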