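#!/usr/bin/env Rscript

# Stage 2: map every simulated small-RNA library to the reporter with the
# four-tier prioritized cascade (perfect transcript match; perfect match to
# RNA-seq-supported junction fragments; one-mismatch retry; fine-grained
# fallback scan with a 14-nt minimum match).
#
# Usage: Rscript analysis/02_map_sirna.R [seed]

suppressPackageStartupMessages(library(spliceReporter))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
sim <- "results/sim"
out <- "results/mapping"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

locus <- build_reporter_locus(default_config(seed = seed))
rnaseq <- read_sam(file.path(sim, "rnaseq_WT_T.sam"))

presets <- sub("^sirna_(.*)\\.fa$", "\\1",
               list.files(sim, pattern = "^sirna_.*\\.fa$"))
for (p in presets) {
  reads <- read_fasta(file.path(sim, sprintf("sirna_%s.fa", p)))
  res <- map_library(reads, locus, rnaseq)
  write_sam(res$assignments, locus,
            file.path(out, sprintf("assignments_%s.sam", p)))
  write_tsv_commented(res$assignments,
                      file.path(out, sprintf("assignments_%s.tsv", p)),
                      sprintf("tiered assignments (%s)", p))
  tally <- data.frame(tier = c(names(res$tier_tally), "unmapped", "library_size"),
                      reads = c(as.integer(res$tier_tally),
                                length(res$unmapped), res$library_size))
  write_tsv_commented(tally, file.path(out, sprintf("tier_tally_%s.tsv", p)),
                      sprintf("tier tally (%s)", p))
  cat(sprintf("%-10s library %6d | tiers %s | unmapped %d\n", p,
              res$library_size,
              paste(res$tier_tally, collapse = "/"), length(res$unmapped)))
}
cat("\nError-free libraries resolve entirely at tiers 1-2; junction-spanning\n")
cat("reads land on the junction fragments (tier 2).\n")
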