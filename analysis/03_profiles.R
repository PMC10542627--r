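#!/usr/bin/env Rscript

# Stage 3: size-class/strand RPM profiles, coverage-per-million tracks, and
# cross-genotype comparisons of the mapped small-RNA libraries.
#
# Usage: Rscript analysis/03_profiles.R [seed]

suppressPackageStartupMessages(library(spliceReporter))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L
mapdir <- "results/mapping"
out <- "results/profiles"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

locus <- build_reporter_locus(default_config(seed = seed))

presets <- sub("^tier_tally_(.*)\\.tsv$", "\\1",
               list.files(mapdir, pattern = "^tier_tally_"))
profiles <- list()
for (p in presets) {
  a <- read_tsv_commented(file.path(mapdir, sprintf("assignments_%s.tsv", p)))
  tally <- read_tsv_commented(file.path(mapdir, sprintf("tier_tally_%s.tsv", p)))
  lib <- tally$reads[tally$tier == "library_size"]
  if (lib == 0) {
    cat(sprintf("%-10s empty library (all siRNAs eliminated)\n", p))
    profiles[[p]] <- NULL
    next
  }
  prof <- size_strand_table(a, lib, sample = p)
  profiles[[p]] <- prof
  write_tsv_commented(as.data.frame(prof),
                      file.path(out, sprintf("profile_%s.tsv", p)),
                      sprintf("size/strand RPM (%s)", p))
  for (lc in c("21", "22", "24", "all")) {
    tr <- coverage_track(a, locus, lib, length_class = lc, sample = p)
    write_bedgraph(tr, file.path(out, sprintf("coverage_%s_%s.bedgraph", p, lc)))
  }
  cds <- locus$regions$gfp_cds
  up <- sort(locus$splice_pairs$donor)           # AU donor .. GU donor span
  trall <- coverage_track(a, locus, lib)
  cat(sprintf("%-10s modal %s nt | total RPM %8.0f | CDS/upstream coverage %4.1fx | antisense %.2f\n",
              p, modal_length(prof), sum(prof$rpm),
              mean(trall$values[(cds[1] + 1):cds[2]]) /
                max(mean(trall$values[(up[1] + 1):up[2]]), 1e-9),
              sum(prof$rpm[prof$strand == "-"]) / sum(prof$rpm)))
}

if (!is.null(profiles$WT_T)) {
  for (p in setdiff(names(profiles), "WT_T")) {
    cmp <- compare_profiles(profiles[[p]], profiles$WT_T)
    write_tsv_commented(cmp, file.path(out, sprintf("compare_%s_vs_WT_T.tsv", p)),
                        sprintf("RPM comparison %s vs WT_T", p))
    cat(sprintf("total RPM ratio %s / WT_T = %.2f\n", p, attr(cmp, "total_ratio")))
  }
}
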