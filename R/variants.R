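#' Scan a mature transcript for its effective open reading frame
#'
#' Models translation initiation on the reporter transcripts: the scan
#' chooses the 5'-most ATG that lies upstream of, and in frame with, the
#' standard (annotated) start codon if one exists, otherwise the standard
#' start itself, then reads codons through to the CDS end. A transcript is
#' translatable when no stop codon interrupts the frame before the final
#' (terminator) codon of the CDS.
#'
#' @param mature_sequence mature transcript sequence (sense, DNA alphabet).
#' @param standard_start_offset 0-based offset of the standard start codon in
#'   `mature_sequence`.
#' @param cds_length CDS length in nt from the standard start (multiple of 3);
#'   defaults to the remaining transcript length truncated to whole codons.
#' @return an `orf_report` list: `start_used`, `stop_found`, `stop_position`
#'   (0-based offset of the first in-frame stop, `NA` if none),
#'   `peptide_length` (codons before the first stop), `n_terminal_extension`
#'   (codons gained relative to the standard start), `translatable`.
#' @export
orf_scan <- function(mature_sequence, standard_start_offset, cds_length = NULL) {
  n <- nchar(mature_sequence)
  if (n < 3L) {
    sr_stop("sequence shorter than one codon", "sr_validation_error")
  }
  std <- as.integer(standard_start_offset)
  if (std < 0L || std + 3L > n) {
    sr_stop("standard_start_offset out of range", "sr_validation_error")
  }
  if (is.null(cds_length)) {
    cds_length <- ((n - std) %/% 3L) * 3L
  }
  cds_length <- as.integer(cds_length)
  if (cds_length %% 3L != 0L || std + cds_length > n) {
    sr_stop("cds_length must be a multiple of 3 within the sequence",
            "sr_validation_error")
  }
  cds_end <- std + cds_length

  # 5'-most upstream in-frame ATG (search bounded to the mature transcript)
  start_used <- std
  if (std >= 3L) {
    cand <- seq.int(std %% 3L, std - 3L, by = 3L)
    hits <- cand[substring(mature_sequence, cand + 1L, cand + 3L) == "ATG"]
    if (length(hits)) start_used <- hits[1]
  }

  codons <- codon_split(substr0(mature_sequence, start_used, cds_end))
  n_codons <- length(codons)
  stop_idx <- which(codons %in% STOP_CODONS)
  if (length(stop_idx)) {
    first <- stop_idx[1]
    stop_position <- start_used + 3L * (first - 1L)
    premature <- first < n_codons
    peptide_length <- first - 1L
  } else {
    first <- NA_integer_
    stop_position <- NA_integer_
    premature <- FALSE
    peptide_length <- n_codons
  }

  structure(list(
    start_used = start_used,
    stop_found = length(stop_idx) > 0L,
    stop_position = stop_position,
    peptide_length = peptide_length,
    n_terminal_extension = (std - start_used) %/% 3L,
    translatable = !premature
  ), class = "orf_report")
}

# Which splice-pair gap, if any, a (gap_start, gap_end) pair matches.
match_junction <- function(locus, gap_start, gap_end) {
  sp <- locus$splice_pairs
  lab <- rep(NA_character_, length(gap_start))
  for (i in seq_len(nrow(sp))) {
    hit <- !is.na(gap_start) & gap_start == sp$donor[i] & gap_end == sp$acceptor[i]
    lab[hit] <- if (sp$site_class[i] == "canonical_GU_AG") "gu_ag" else "au_ac"
  }
  lab
}

#' Classify alignments by the splice variant they support
#'
#' A split read whose gap equals the AU-AC (GU-AG) donor-acceptor pair
#' supports the corresponding spliced variant. A contiguous read overlapping
#' a position found only in the unspliced form (the interior of the GU-AG
#' intron, which both spliced variants remove) supports the unspliced
#' pre-mRNA. Everything else is ambiguous: exonic contiguous reads are
#' compatible with several variants, and gaps matching neither pair support
#' no annotated variant.
#'
#' @param alignments alignment data.frame (see [alignment_frame()]).
#' @param locus a `reporter_locus`.
#' @return character vector of labels in
#'   `c("unspliced", "gu_ag", "au_ac", "ambiguous")`, one per alignment.
#' @export
classify_reads <- function(alignments, locus) {
  n <- nrow(alignments)
  if (n == 0) return(character(0))
  lab <- rep("ambiguous", n)
  split <- !is.na(alignments$start2)
  jl <- match_junction(locus, alignments$end1[split], alignments$start2[split])
  lab[split] <- ifelse(is.na(jl), "ambiguous", jl)
  gu <- locus$splice_pairs[locus$splice_pairs$site_class == "canonical_GU_AG", ]
  uniq_s <- gu$donor
  uniq_e <- gu$acceptor
  contig <- !split
  hits_unique <- contig &
    alignments$start1 < uniq_e & alignments$end1 > uniq_s
  lab[hits_unique] <- "unspliced"
  lab
}

#' Quantify splice-variant proportions from alignments
#'
#' Counts reads by [classify_reads()] and reports proportions over the
#' informative (non-ambiguous) reads only; ambiguous reads are counted but
#' never redistributed.
#'
#' @param alignments alignment data.frame.
#' @param locus a `reporter_locus`.
#' @return a `variant_proportions` list: `counts` (named, incl. ambiguous),
#'   `proportions` over the three informative classes (`NA` and
#'   `defined = FALSE` when no read is informative), `n_informative`.
#' @export
variant_proportions <- function(alignments, locus) {
  lab <- classify_reads(alignments, locus)
  lv <- c("unspliced", "gu_ag", "au_ac", "ambiguous")
  counts <- table(factor(lab, levels = lv))
  counts <- stats::setNames(as.integer(counts), lv)
  inf <- counts[c("unspliced", "gu_ag", "au_ac")]
  n_inf <- sum(inf)
  if (n_inf > 0) {
    props <- inf / n_inf
    defined <- TRUE
  } else {
    props <- stats::setNames(rep(NA_real_, 3), names(inf))
    defined <- FALSE
  }
  structure(list(counts = counts, proportions = props,
                 n_informative = n_inf, defined = defined),
            class = "variant_proportions")
}
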