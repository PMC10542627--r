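#' Run the full reporter pipeline into a directory
#'
#' Executes the five stages end to end: simulate (locus, RNA-seq alignments,
#' genotype-dependent small RNAs), map-sirna (prioritized cascade),
#' profile (size/strand RPM tables and coverage-per-million tracks),
#' as-test (differential AS events, preset vs control, merged triplicates),
#' and quantify-variants (splice-variant proportions and ORF reports).
#' Every output is listed in a manifest with its md5 checksum; the same
#' config and seed reproduce identical checksums. The single seed fans out
#' to per-stage and per-replicate seeds so stages are individually
#' reproducible.
#'
#' @param out_dir output directory (created; existing files overwritten).
#' @param cfg a `sim_config`.
#' @param preset genotype preset for the focal sample.
#' @param control_preset genotype preset of the comparison group for the
#'   AS stage.
#' @param n_replicates biological replicates per group in the AS stage.
#' @param alpha,min_total AS-test parameters (see [detect_events()]).
#' @return invisibly, a list with `manifest` (data.frame: file, stage, md5),
#'   `log` (per-stage timings), and the in-memory stage results.
#' @export
run_pipeline <- function(out_dir, cfg = default_config(), preset = "WT_T",
                         control_preset = "WT_T", n_replicates = 3L,
                         alpha = 0.05, min_total = 10) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(file = character(0), stage = character(0),
                         stringsAsFactors = FALSE)
  log <- list()
  emit <- function(file, stage) {
    manifest[nrow(manifest) + 1L, ] <<- c(file, stage)
  }
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      sr_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
              "sr_stage_error")
    })
    log[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    res
  }

  # --- simulate -------------------------------------------------------------
  sim <- run_stage("simulate", function() {
    locus <- build_reporter_locus(cfg)
    rnaseq <- simulate_rnaseq(locus, cfg)
    sirna <- simulate_sirna(locus, cfg, preset)
    write_fasta(stats::setNames(locus$sequence, locus$name),
                file.path(out_dir, "locus.fa"))
    emit("locus.fa", "simulate")
    write_sam(rnaseq, locus, file.path(out_dir, "rnaseq.sam"))
    emit("rnaseq.sam", "simulate")
    write_fasta(stats::setNames(sirna$sequence, sirna$read_id),
                file.path(out_dir, "sirna.fa"))
    emit("sirna.fa", "simulate")
    write_tsv_commented(sirna[, setdiff(names(sirna), "sequence")],
                        file.path(out_dir, "sirna_truth.tsv"),
                        "small-RNA simulation truth")
    emit("sirna_truth.tsv", "simulate")
    list(locus = locus, rnaseq = rnaseq, sirna = sirna)
  })

  # --- map-sirna ------------------------------------------------------------
  mapped <- run_stage("map-sirna", function() {
    res <- map_library(sim$sirna, sim$locus, sim$rnaseq)
    write_sam(res$assignments, sim$locus, file.path(out_dir, "sirna_mapped.sam"))
    emit("sirna_mapped.sam", "map-sirna")
    write_tsv_commented(res$assignments, file.path(out_dir, "sirna_assignments.tsv"),
                        "small-RNA assignments (tiered)")
    emit("sirna_assignments.tsv", "map-sirna")
    tally <- data.frame(tier = names(res$tier_tally),
                        reads = as.integer(res$tier_tally))
    tally <- rbind(tally, data.frame(tier = c("unmapped", "library_size"),
                                     reads = c(length(res$unmapped),
                                               res$library_size)))
    write_tsv_commented(tally, file.path(out_dir, "tier_tally.tsv"),
                        "mapping tier tally")
    emit("tier_tally.tsv", "map-sirna")
    res
  })

  # --- profile --------------------------------------------------------------
  run_stage("profile", function() {
    L <- nchar(sim$locus$sequence)
    if (mapped$library_size > 0) {
      prof <- size_strand_table(mapped$assignments, mapped$library_size,
                                sample = preset)
    } else {
      # an empty library (e.g. rdr6) still yields a valid, all-zero profile
      prof <- data.frame(expand.grid(length = 18:30, strand = c("+", "-"),
                                     stringsAsFactors = FALSE),
                         count = 0, rpm = 0)
    }
    write_tsv_commented(prof, file.path(out_dir, "size_strand_profile.tsv"),
                        sprintf("size/strand RPM profile (%s)", preset))
    emit("size_strand_profile.tsv", "profile")
    for (lc in c("21", "22", "24", "all")) {
      fn <- sprintf("coverage_%s.bedgraph", lc)
      if (mapped$library_size > 0) {
        tr <- coverage_track(mapped$assignments, sim$locus,
                             mapped$library_size, length_class = lc,
                             sample = preset)
      } else {
        tr <- structure(list(values = numeric(L), sample = preset,
                             length_class = lc, strand = "both",
                             reference = sim$locus$name),
                        class = "coverage_track")
      }
      write_bedgraph(tr, file.path(out_dir, fn))
      emit(fn, "profile")
    }
    NULL
  })

  # --- as-test --------------------------------------------------------------
  as_res <- run_stage("as-test", function() {
    grp <- function(which_preset, base) {
      lapply(seq_len(n_replicates), function(r) {
        c2 <- apply_preset(cfg, which_preset)
        c2$seed <- cfg$seed + base + r
        a <- simulate_rnaseq(sim$locus, c2, sequences = FALSE)
        a[a$mate == 1L, , drop = FALSE]   # one observation per fragment
      })
    }
    res <- detect_events(grp(control_preset, 1000L), grp(preset, 2000L),
                         sim$locus, alpha = alpha, min_total = min_total)
    write_tsv_commented(res, file.path(out_dir, "as_events.tsv"),
                        sprintf("AS events: %s vs %s", preset, control_preset))
    emit("as_events.tsv", "as-test")
    res
  })

  # --- quantify-variants ----------------------------------------------------
  vq <- run_stage("quantify-variants", function() {
    vp <- variant_proportions(sim$rnaseq, sim$locus)
    variants <- enumerate_splice_variants(sim$locus)
    vtab <- data.frame(
      variant = names(vp$counts),
      count = as.integer(vp$counts),
      proportion = c(vp$proportions, NA),
      translatable = c(vapply(variants, `[[`, logical(1), "translatable"), NA))
    write_tsv_commented(vtab, file.path(out_dir, "variant_proportions.tsv"),
                        "splice-variant read counts and proportions")
    emit("variant_proportions.tsv", "quantify-variants")
    orf <- do.call(rbind, lapply(variants, function(v) {
      data.frame(variant = v$label, start_used = v$orf$start_used,
                 stop_found = v$orf$stop_found,
                 peptide_length = v$orf$peptide_length,
                 n_terminal_extension = v$orf$n_terminal_extension,
                 translatable = v$orf$translatable)
    }))
    write_tsv_commented(orf, file.path(out_dir, "orf_reports.tsv"),
                        "ORF scan of the three mature transcripts")
    emit("orf_reports.tsv", "quantify-variants")
    vp
  })

  manifest$md5 <- unname(tools::md5sum(file.path(out_dir, manifest$file)))
  write_tsv_commented(manifest, file.path(out_dir, "manifest.tsv"),
                      "output manifest with md5 checksums")
  log_df <- data.frame(stage = names(log), seconds = unlist(log),
                       seed = cfg$seed, preset = preset)
  write_tsv_commented(log_df, file.path(out_dir, "run_log.tsv"), "stage log")

  invisible(list(manifest = manifest, log = log, locus = sim$locus,
                 mapping = mapped, as_events = as_res,
                 variant_proportions = vq))
}
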