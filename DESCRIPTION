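Package: spliceReporter
Title: Simulation and Analysis of an Alternatively Spliced GFP Reporter
    and Its siRNA-Mediated Silencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to emulate and analyse an alternatively spliced GFP
    reporter transgene of the kind used in Arabidopsis splicing and
    silencing screens. The package deterministically constructs a
    synthetic reporter locus (enhancer, minimal promoter, GFP CDS) with
    one canonical GU-AG and one noncanonical AU-AC splice-site pair,
    simulates RNA-seq alignments and genotype-dependent small-RNA
    populations, maps small RNAs to the reporter with a four-tier
    prioritized cascade (perfect transcript match, junction fragments,
    one-mismatch retry, fine-grained fallback scan), builds
    reads-per-million size-class/strand profiles and coverage tracks,
    detects differential alternative-splicing events (intron retention,
    exon skipping, alternative donor/acceptor) with a signal/background
    Pearson chi-square test on merged replicates, and quantifies splice
    variant proportions and transcript translatability by ORF scanning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
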