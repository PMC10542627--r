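# Overlap width of alignment blocks with a 0-based half-open interval.
# Gap (N) regions of split reads never count.
block_overlap <- function(alignments, lo, hi) {
  ov <- pmax(0L, pmin(alignments$end1, hi) - pmax(alignments$start1, lo))
  split <- !is.na(alignments$start2)
  ov[split] <- ov[split] +
    pmax(0L, pmin(alignments$end2[split], hi) - pmax(alignments$start2[split], lo))
  ov
}

as_count_pair <- function(signal, background) {
  c(signal = as.numeric(signal), background = as.numeric(background))
}

#' Signal/background counts for an intron-retention event
#'
#' Signal measures expression of the intron itself, background that of the
#' flanking exons. Two count modes are provided because read depth over a
#' region can be summarised at read resolution or at base resolution:
#' \describe{
#'   \item{read_count (default)}{each alignment is assigned once, to the
#'     region (intron vs flanking exons) holding the majority of its aligned
#'     bases; intron assignment requires contiguous (non-split) alignments.
#'     Cells are then genuine read counts, which is what a chi-square on
#'     counts assumes.}
#'   \item{mean_depth}{signal is the rounded mean per-base depth over the
#'     intron from non-split alignments, background the rounded mean
#'     per-base depth over the two flanking exons (split reads contribute to
#'     exon depth only).}
#' }
#'
#' @param alignments alignment data.frame.
#' @param intron 0-based half-open interval `c(start, end)`.
#' @param flanking_exons list of two intervals (upstream, downstream).
#' @param mode "read_count" or "mean_depth".
#' @return named numeric `c(signal, background)`.
#' @export
count_ir <- function(alignments, intron, flanking_exons,
                     mode = c("read_count", "mean_depth")) {
  mode <- match.arg(mode)
  if (intron[2] <= intron[1]) {
    sr_stop("zero-width intron", "sr_validation_error")
  }
  split <- !is.na(alignments$start2)
  ov_i <- block_overlap(alignments, intron[1], intron[2])
  ov_i[split] <- 0L                         # intron signal: non-split only
  ov_e <- block_overlap(alignments, flanking_exons[[1]][1], flanking_exons[[1]][2]) +
    block_overlap(alignments, flanking_exons[[2]][1], flanking_exons[[2]][2])

  if (mode == "read_count") {
    sig <- sum(ov_i > ov_e)
    bg <- sum(ov_e > 0 & ov_e >= ov_i)
    return(as_count_pair(sig, bg))
  }
  exon_len <- (flanking_exons[[1]][2] - flanking_exons[[1]][1]) +
    (flanking_exons[[2]][2] - flanking_exons[[2]][1])
  as_count_pair(round(sum(ov_i) / (intron[2] - intron[1])),
                round(sum(ov_e) / exon_len))
}

#' Signal/background counts for an exon-skipping event
#'
#' Signal: split reads whose gap fully contains the exon (skipping reads).
#' Background: split reads using either flanking junction, thereby including
#' the exon. Reads whose gap only partially overlaps the exon count in
#' neither cell.
#'
#' @param alignments alignment data.frame.
#' @param exon 0-based half-open interval.
#' @param flanking_junctions list of two `c(donor, acceptor)` pairs (the
#'   inclusion junctions left and right of the exon).
#' @return named numeric `c(signal, background)`.
#' @export
count_es <- function(alignments, exon, flanking_junctions) {
  if (length(flanking_junctions) < 2L) {
    sr_stop("exon-skipping event needs two flanking junction candidates",
            "sr_unsupported_event")
  }
  sp <- alignments[!is.na(alignments$start2), , drop = FALSE]
  if (nrow(sp) == 0) return(as_count_pair(0, 0))
  gap_s <- sp$end1; gap_e <- sp$start2
  sig <- sum(gap_s <= exon[1] & gap_e >= exon[2])
  bg <- 0L
  for (j in flanking_junctions) {
    bg <- bg + sum(gap_s == j[1] & gap_e == j[2])
  }
  as_count_pair(sig, bg)
}

#' Signal/background counts for an alternative donor/acceptor event
#'
#' Signal: split reads whose gap equals the donor-acceptor pair exactly.
#' Background (shared-site rule): split reads sharing the donor or the
#' acceptor but pairing it with a different partner; with
#' `background = "all_split"`, all other split reads at the locus.
#'
#' @param alignments alignment data.frame.
#' @param pair `c(donor, acceptor)` (0-based; gap interval of the junction).
#' @param background "shared_site" or "all_split".
#' @return named numeric `c(signal, background)`.
#' @export
count_altda <- function(alignments, pair,
                        background = c("shared_site", "all_split")) {
  background <- match.arg(background)
  sp <- alignments[!is.na(alignments$start2), , drop = FALSE]
  if (nrow(sp) == 0) return(as_count_pair(0, 0))
  gap_s <- sp$end1; gap_e <- sp$start2
  exact <- gap_s == pair[1] & gap_e == pair[2]
  bg <- if (background == "shared_site") {
    sum((gap_s == pair[1] | gap_e == pair[2]) & !exact)
  } else {
    sum(!exact)
  }
  as_count_pair(sum(exact), bg)
}

#' Merge replicate count pairs by accumulation
#'
#' Replicates are pooled by element-wise summation before testing, which
#' raises power when per-event read numbers are small.
#'
#' @param pairs list of `c(signal, background)` pairs.
#' @return a single summed `c(signal, background)`.
#' @export
merge_replicates <- function(pairs) {
  if (length(pairs) == 0) {
    sr_stop("cannot merge an empty replicate list", "sr_validation_error")
  }
  colSums(do.call(rbind, pairs))
}

#' Pearson chi-square test on a signal/background 2x2 table
#'
#' Compares the signal proportion between a control and a treatment group on
#' the 2x2 table `[[s_c, b_c], [s_t, b_t]]` with the closed-form Pearson
#' statistic `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, one degree of freedom,
#' no continuity correction. A table with any zero marginal total carries no
#' information about differential preference and returns `chi2 = 0`,
#' `p = 1`. P-values are deliberately not corrected for multiple testing.
#'
#' @param control,treatment `c(signal, background)` count pairs.
#' @param alpha significance threshold.
#' @return an `as_test` list: `chi2`, `df`, `p_value`, `direction` (sign of
#'   the treatment-minus-control signal fraction), `significant`, plus the
#'   input counts.
#' @export
chi2_test <- function(control, treatment, alpha = 0.05) {
  a <- control[["signal"]]; b <- control[["background"]]
  cc <- treatment[["signal"]]; d <- treatment[["background"]]
  if (any(c(a, b, cc, d) < 0)) {
    sr_stop("counts must be non-negative", "sr_validation_error")
  }
  n <- a + b + cc + d
  margins <- c(a + b, cc + d, a + cc, b + d)
  if (any(margins == 0)) {
    chi2 <- 0
    p <- 1
    direction <- 0
  } else {
    chi2 <- n * (a * d - b * cc)^2 / prod(margins)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
    direction <- sign(cc / (cc + d) - a / (a + b))
  }
  structure(list(chi2 = unname(chi2), df = 1L, p_value = unname(p),
                 direction = unname(direction),
                 significant = p < alpha,
                 control = control, treatment = treatment, alpha = alpha),
            class = "as_test")
}

# IR/ES/altDA candidate events derived from the locus annotation plus the
# junctions observed in the merged alignments.
enumerate_as_events <- function(locus, alignments, flank_width = 100L) {
  L <- nchar(locus$sequence)
  sp <- locus$splice_pairs
  events <- list()

  for (i in seq_len(nrow(sp))) {
    d <- sp$donor[i]; a <- sp$acceptor[i]
    events[[length(events) + 1L]] <- list(
      kind = "IR", id = sprintf("IR_%d_%d", d, a),
      target = c(d, a),
      flanking_exons = list(c(max(locus$tss, d - flank_width), d),
                            c(a, min(L, a + flank_width))))
  }

  # skippable exons: components of a larger gap minus a nested smaller gap
  for (i in seq_len(nrow(sp))) for (j in seq_len(nrow(sp))) {
    if (i == j) next
    if (sp$donor[i] <= sp$donor[j] && sp$acceptor[i] >= sp$acceptor[j] &&
        (sp$donor[i] < sp$donor[j] || sp$acceptor[i] > sp$acceptor[j])) {
      pieces <- list(c(sp$donor[i], sp$donor[j]),
                     c(sp$acceptor[j], sp$acceptor[i]))
      for (ex in Filter(function(x) x[2] > x[1], pieces)) {
        flank_j <- list()
        for (k in seq_len(nrow(sp))) {
          if (sp$acceptor[k] == ex[1] || sp$donor[k] == ex[2]) {
            flank_j[[length(flank_j) + 1L]] <- c(sp$donor[k], sp$acceptor[k])
          }
        }
        events[[length(events) + 1L]] <- list(
          kind = "ES", id = sprintf("ES_%d_%d", ex[1], ex[2]),
          target = ex, flanking_junctions = flank_j)
      }
    }
  }

  observed <- junctions_from_alignments(alignments)
  for (i in seq_len(nrow(observed))) {
    d <- observed$donor[i]; a <- observed$acceptor[i]
    events[[length(events) + 1L]] <- list(
      kind = "altDA", id = sprintf("altDA_%d_%d", d, a), target = c(d, a))
  }
  events
}

#' Detect differential alternative-splicing events between two groups
#'
#' Enumerates candidate IR, ES and altDA events from the locus annotation
#' plus observed junctions, accumulates signal/background counts across the
#' biological replicates of each group, and tests every event with the
#' Pearson chi-square on the resulting 2x2 table. Events whose pooled total
#' count falls below `min_total` are reported untested. P-values are not
#' corrected for multiple testing.
#'
#' @param control_reps,treatment_reps lists of alignment data.frames, one
#'   per biological replicate.
#' @param locus a `reporter_locus`.
#' @param alpha significance threshold on the uncorrected p-value.
#' @param min_total minimum pooled signal+background across both groups.
#' @param ir_mode passed to [count_ir()].
#' @param altda_background passed to [count_altda()].
#' @param flank_width width (nt) of the IR flanking-exon windows.
#' @return data.frame, one row per candidate event: kind, id, target
#'   coordinates, the four merged counts, `chi2`, `p_value`, `direction`,
#'   `significant`, `tested`, `note`.
#' @export
detect_events <- function(control_reps, treatment_reps, locus,
                          alpha = 0.05, min_total = 10,
                          ir_mode = "read_count",
                          altda_background = "shared_site",
                          flank_width = 100L) {
  all_aln <- do.call(rbind, lapply(c(control_reps, treatment_reps),
                                   function(x) x[, c("read_id", "strand",
                                                     "start1", "end1",
                                                     "start2", "end2")]))
  events <- enumerate_as_events(locus, all_aln, flank_width)

  count_one <- function(ev, aln) {
    switch(ev$kind,
      IR = count_ir(aln, ev$target, ev$flanking_exons, mode = ir_mode),
      ES = count_es(aln, ev$target, ev$flanking_junctions),
      altDA = count_altda(aln, ev$target, background = altda_background))
  }

  rows <- lapply(events, function(ev) {
    row <- data.frame(kind = ev$kind, id = ev$id,
                      target_start = ev$target[1], target_end = ev$target[2],
                      s_ctrl = NA_real_, b_ctrl = NA_real_,
                      s_trt = NA_real_, b_trt = NA_real_,
                      chi2 = NA_real_, p_value = NA_real_,
                      direction = NA_real_, significant = FALSE,
                      tested = FALSE, note = "", stringsAsFactors = FALSE)
    ctrl <- tryCatch(
      merge_replicates(lapply(control_reps, count_one, ev = ev)),
      sr_unsupported_event = function(e) NULL)
    if (is.null(ctrl)) {
      row$note <- "unsupported: fewer than two flanking junctions"
      return(row)
    }
    trt <- merge_replicates(lapply(treatment_reps, count_one, ev = ev))
    row$s_ctrl <- ctrl[["signal"]]; row$b_ctrl <- ctrl[["background"]]
    row$s_trt <- trt[["signal"]]; row$b_trt <- trt[["background"]]
    if (sum(ctrl) + sum(trt) < min_total) {
      row$note <- "below min_total"
      return(row)
    }
    t <- chi2_test(ctrl, trt, alpha = alpha)
    row$chi2 <- t$chi2; row$p_value <- t$p_value
    row$direction <- t$direction; row$significant <- t$significant
    row$tested <- TRUE
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
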