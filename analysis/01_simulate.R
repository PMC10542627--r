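#!/usr/bin/env Rscript

# Stage 1: build the synthetic reporter locus and simulate the study data.
#
# Emulates the reporter transgene (enhancer 1277 bp / minimal promoter 91 bp /
# GFP CDS 720 bp; canonical GU-AG and noncanonical AU-AC splice pairs) and
# generates (i) wild-type RNA-seq alignments over the three splice variants
# and (ii) genotype-dependent small-RNA libraries for the genotypes of
# interest. Everything is deterministic in the seed.
#
# Usage: Rscript analysis/01_simulate.R [seed]

suppressPackageStartupMessages(library(spliceReporter))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

presets <- c("WT_T", "coi1", "rdr6", "dcl4", "cwc16a", "coi1_zch1")

cfg <- default_config(seed = seed)
locus <- build_reporter_locus(cfg)
write_fasta(stats::setNames(locus$sequence, locus$name),
            file.path(out, "locus.fa"))

cat("Reporter locus:\n")
print(locus)

rnaseq <- simulate_rnaseq(locus, cfg)
write_sam(rnaseq, locus, file.path(out, "rnaseq_WT_T.sam"))
cat(sprintf("\nRNA-seq: %d read pairs (%d split alignments over junctions)\n",
            cfg$n_rnaseq_read_pairs, sum(!is.na(rnaseq$start2))))

for (p in presets) {
  s <- simulate_sirna(locus, cfg, p)
  write_fasta(stats::setNames(s$sequence, s$read_id),
              file.path(out, sprintf("sirna_%s.fa", p)))
  write_tsv_commented(s[, setdiff(names(s), "sequence")],
                      file.path(out, sprintf("sirna_truth_%s.tsv", p)),
                      sprintf("siRNA truth (%s)", p))
  cat(sprintf("siRNA %-10s %6d reads; modal length %s\n", p, nrow(s),
              if (nrow(s)) names(which.max(table(s$length))) else "-"))
}

cat(sprintf("\nSeed %d; outputs under %s/\n", seed, out))
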