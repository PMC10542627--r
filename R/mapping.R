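#' Observed splice junctions from RNA-seq alignments
#'
#' Tabulates the distinct donor-acceptor gaps carried by split alignments.
#'
#' @param alignments alignment data.frame.
#' @param min_support minimum number of supporting split reads.
#' @return data.frame with `donor`, `acceptor`, `support`, ordered by donor.
#' @export
junctions_from_alignments <- function(alignments, min_support = 1L) {
  split <- alignments[!is.na(alignments$start2), , drop = FALSE]
  if (nrow(split) == 0) {
    return(data.frame(donor = integer(0), acceptor = integer(0),
                      support = integer(0)))
  }
  key <- paste(split$end1, split$start2)
  tab <- table(key)
  parts <- strsplit(names(tab), " ", fixed = TRUE)
  df <- data.frame(donor = as.integer(vapply(parts, `[[`, character(1), 1L)),
                   acceptor = as.integer(vapply(parts, `[[`, character(1), 2L)),
                   support = as.integer(tab))
  df <- df[df$support >= min_support, , drop = FALSE]
  df <- df[order(df$donor, df$acceptor), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build junction-spanning fragments
#'
#' For each RNA-seq-supported junction, concatenates `flank` nt of exonic
#' sequence on each side of the donor-acceptor gap. Small-RNA reads that
#' straddle the concatenation point are junction-derived; their fragment
#' coordinates project back to two vector blocks.
#'
#' @param locus a `reporter_locus`.
#' @param junctions data.frame with `donor`, `acceptor`
#'   (see [junctions_from_alignments()]).
#' @param flank flank width in nt; must be at least the longest small RNA
#'   minus one so that every junction-spanning read fits.
#' @return list of `junction_fragment` objects: `donor`, `acceptor`,
#'   `sequence` (length `2 * flank`), `flank`, `left_start`.
#' @export
build_junction_fragments <- function(locus, junctions, flank = 29L) {
  L <- nchar(locus$sequence)
  lapply(seq_len(nrow(junctions)), function(i) {
    d <- junctions$donor[i]; a <- junctions$acceptor[i]
    if (d - flank < 0 || a + flank > L || d >= a) {
      sr_stop(sprintf("junction (%d, %d) with flank %d outside the locus",
                      d, a, flank),
              "sr_validation_error")
    }
    structure(list(
      donor = d, acceptor = a, flank = as.integer(flank),
      left_start = d - as.integer(flank),
      sequence = paste0(substr0(locus$sequence, d - flank, d),
                        substr0(locus$sequence, a, a + flank))
    ), class = "junction_fragment")
  })
}

# All (including overlapping) 0-based start positions of a fixed pattern in
# `subject`. Reads containing N never match exactly (N is not a wildcard).
exact_positions <- function(pattern, subject) {
  if (grepl("N", pattern, fixed = TRUE)) return(integer(0))
  out <- integer(0)
  k <- nchar(pattern)
  L <- nchar(subject)
  from <- 1L
  while (from <= L - k + 1L) {
    m <- regexpr(pattern, substr(subject, from, L), fixed = TRUE)
    if (m == -1L) break
    p <- from + as.integer(m) - 1L        # 1-based match start
    out <- c(out, p - 1L)
    from <- p + 1L                        # resume inside the match: overlaps
  }
  out
}

# Mismatch count of the read at every placement along the subject
# (integer-encoded sequences; N codes differ between read and subject so an
# N always counts as a mismatch).
mm_vector <- function(r_int, s_int) {
  k <- length(r_int)
  n <- length(s_int) - k + 1L
  if (n <= 0L) return(integer(0))
  mm <- integer(n)
  for (j in seq_len(k)) {
    mm <- mm + (s_int[j:(j + n - 1L)] != r_int[j])
  }
  mm
}

# Placements with exactly one substitution, 0-based starts.
one_mm_positions <- function(r_int, s_int) {
  which(mm_vector(r_int, s_int) == 1L) - 1L
}

# Hits of read (both orientations) on one linear subject.
# mode "exact": perfect matches; mode "one_mm": exactly one substitution.
scan_subject <- function(rd, subject, mode) {
  if (mode == "exact") {
    f <- exact_positions(rd$seq, subject$seq)
    r <- exact_positions(rd$seq_rc, subject$seq)
    mmf <- rep(0L, length(f)); mmr <- rep(0L, length(r))
  } else {
    f <- one_mm_positions(rd$int, subject$int)
    r <- one_mm_positions(rd$int_rc, subject$int)
    mmf <- rep(1L, length(f)); mmr <- rep(1L, length(r))
  }
  data.frame(start = c(f, r), mismatches = c(mmf, mmr),
             strand = rep(c("+", "-"), c(length(f), length(r))),
             stringsAsFactors = FALSE)
}

#' Precompile search subjects for the mapping cascade
#'
#' Encodes the tier-1 transcript, the junction fragments and the full vector
#' once (plain string plus integer encoding), so that mapping a whole
#' library does not redo the conversions per read.
#'
#' @param locus a `reporter_locus`.
#' @param fragments list from [build_junction_fragments()].
#' @return opaque list consumed by [assign_read()].
#' @export
compile_subjects <- function(locus, fragments = list()) {
  enc <- function(s) list(seq = s, int = dna_int(s, n_code = 5L))
  tx <- canonical_transcript(locus)
  list(
    tx = c(enc(tx$sequence), offset = tx$offset),
    frag_enc = lapply(fragments, function(fr) enc(fr$sequence)),
    fragments = fragments,
    locus = enc(locus$sequence)
  )
}

# Best partial ungapped alignments of a read against the vector: any
# diagonal placement, at most one substitution, at least `min_match`
# matching bases (the fine-scanning fallback). Returns all top-scoring
# placements (score = matched bases). Completeness with the diagonal
# prefilter: a window with <= 1 substitution and >= min_match matches
# contains an exact run of >= ceiling((min_match - 1) / 2) >= 7 bases, so
# only diagonals carrying an exact 7-mer seed can qualify.
scan_partial <- function(read_str, read_int, subject, min_match = 14L) {
  locus_int <- subject$int
  rl <- length(read_int)
  L <- length(locus_int)
  q <- 7L
  cand <- integer(0)
  for (i in 0:(rl - q)) {
    for (p in exact_positions(substr(read_str, i + 1L, i + q), subject$seq)) {
      cand <- c(cand, p - i)
    }
  }
  cand <- sort(unique(cand))
  cand <- cand[cand >= -(rl - min_match) & cand <= L - min_match]
  best_score <- min_match - 1L
  hits <- list()
  for (d in cand) {
    i0 <- max(0L, -d)
    i1 <- min(rl, L - d)
    if (i1 - i0 < min_match) next
    idx <- (i0 + 1L):i1
    mism <- which(read_int[idx] != locus_int[idx + d])
    seg_len <- length(idx)
    if (length(mism) == 0) {
      score <- seg_len
      w0 <- 1L; w1 <- seg_len; nmm <- 0L
    } else {
      ms <- c(0L, mism, seg_len + 1L)
      gains <- ms[-(1:2)] - ms[seq_len(length(ms) - 2L)] - 2L  # matches per 1-mm window
      k <- which.max(gains)
      score <- gains[k]
      # trim window edges that are mismatches
      w0 <- ms[k] + 1L
      w1 <- ms[k + 2L] - 1L
      nmm <- 1L
      if (w0 == mism[k]) { w0 <- w0 + 1L; nmm <- 0L }
      if (w1 == mism[k]) { w1 <- w1 - 1L; nmm <- 0L }
      if (w1 - w0 + 1L - nmm < min_match) next
    }
    if (score < min_match || score < best_score) next
    ref_start <- d + i0 + (w0 - 1L)       # 0-based on locus
    ref_end <- d + i0 + w1
    hit <- list(start = ref_start, end = ref_end, mismatches = nmm,
                score = score)
    if (score > best_score) {
      best_score <- score
      hits <- list(hit)
    } else {
      hits <- c(hits, list(hit))
    }
  }
  hits
}

# Encode a DNA string as integers; N becomes 0 on the read side and 5 on the
# subject side, so N never matches anything.
dna_int <- function(x, n_code = 0L) {
  map <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  v <- map[strsplit(toupper(x), "", fixed = TRUE)[[1]]]
  v[is.na(v)] <- n_code
  unname(v)
}

#' Assign one small-RNA read by the prioritized cascade
#'
#' Tier 1: perfect match (either orientation) to the contiguous reporter
#' transcript. Tier 2: perfect match to an RNA-seq-supported
#' junction-spanning fragment, straddling the junction. Tier 3: tiers 1-2
#' retried allowing one substitution (transcript first, then fragments).
#' Tier 4: fine-grained fallback scan of the whole vector - full-length
#' placement with at most one substitution, then any partial ungapped
#' placement with at least 14 matching bases. The first tier with a hit
#' wins and all its hit positions are returned; fragment hits are projected
#' to vector coordinates as two blocks.
#'
#' @param read read sequence (A/C/G/T/N).
#' @param locus a `reporter_locus`.
#' @param fragments list from [build_junction_fragments()].
#' @param min_match minimum matched length for the tier-4 partial scan.
#' @param subjects precompiled search subjects from [compile_subjects()];
#'   built on the fly when omitted.
#' @return data.frame of hits: `tier`, `strand`, `start1..end2`,
#'   `mismatches`, `n_hits`; zero rows when unmapped.
#' @export
assign_read <- function(read, locus, fragments = list(), min_match = 14L,
                        subjects = NULL) {
  read <- toupper(read)
  if (grepl("[^ACGTN]", read)) {
    sr_stop("read contains characters outside ACGTN", "sr_validation_error")
  }
  if (is.null(subjects)) subjects <- compile_subjects(locus, fragments)
  rl <- nchar(read)
  read_rc <- revcomp(read)
  rd <- list(seq = read, seq_rc = read_rc,
             int = dna_int(read), int_rc = dna_int(read_rc))
  tx <- subjects$tx

  as_hits <- function(tier, strand, s1, e1, s2 = NA_integer_,
                      e2 = NA_integer_, mm = 0L) {
    data.frame(tier = tier, strand = strand,
               start1 = as.integer(s1), end1 = as.integer(e1),
               start2 = as.integer(s2), end2 = as.integer(e2),
               mismatches = as.integer(mm), stringsAsFactors = FALSE)
  }

  transcript_hits <- function(mode) {
    h <- scan_subject(rd, tx, mode)
    if (nrow(h) == 0) return(NULL)
    as_hits(NA_integer_, h$strand, tx$offset + h$start,
            tx$offset + h$start + rl, mm = h$mismatches)
  }

  fragment_hits <- function(mode) {
    out <- NULL
    for (fi in seq_along(subjects$fragments)) {
      fr <- subjects$fragments[[fi]]
      h <- scan_subject(rd, subjects$frag_enc[[fi]], mode)
      # must straddle the concatenation point
      h <- h[h$start < fr$flank & h$start + rl > fr$flank, , drop = FALSE]
      if (nrow(h) == 0) next
      left_w <- fr$flank - h$start
      out <- rbind(out, as_hits(
        NA_integer_, h$strand,
        fr$left_start + h$start, fr$donor,
        fr$acceptor, fr$acceptor + (rl - left_w),
        mm = h$mismatches))
    }
    out
  }

  # tier 1 / 2
  h <- transcript_hits("exact")
  if (!is.null(h)) { h$tier <- 1L }
  if (is.null(h)) {
    h <- fragment_hits("exact")
    if (!is.null(h)) h$tier <- 2L
  }
  # tier 3: one mismatch, transcript then fragments
  if (is.null(h)) {
    h <- transcript_hits("one_mm")
    if (is.null(h)) h <- fragment_hits("one_mm")
    if (!is.null(h)) h$tier <- 3L
  }
  # tier 4: whole-vector fallback
  if (is.null(h)) {
    full <- rbind(scan_subject(rd, subjects$locus, "exact"),
                  scan_subject(rd, subjects$locus, "one_mm"))
    if (nrow(full)) {
      best <- min(full$mismatches)
      full <- full[full$mismatches == best, , drop = FALSE]
      h <- as_hits(4L, full$strand, full$start, full$start + rl,
                   mm = full$mismatches)
    } else {
      for (str in c("+", "-")) {
        r_str <- if (str == "+") rd$seq else rd$seq_rc
        r_int <- if (str == "+") rd$int else rd$int_rc
        part <- scan_partial(r_str, r_int, subjects$locus, min_match)
        for (p in part) {
          h <- rbind(h, as_hits(4L, str, p$start, p$end, mm = p$mismatches))
        }
      }
      if (!is.null(h) && nrow(h) > 1) {
        score <- (h$end1 - h$start1) - h$mismatches
        h <- h[score == max(score), , drop = FALSE]
      }
    }
  }

  if (is.null(h)) {
    h <- as_hits(integer(0), character(0), integer(0), integer(0),
                 integer(0), integer(0), integer(0))
  }
  h$n_hits <- rep(nrow(h), nrow(h))
  rownames(h) <- NULL
  h
}

#' Map a small-RNA library with the prioritized cascade
#'
#' Derives the supported junction set from RNA-seq alignments, applies the
#' read-length filter, and assigns every read via [assign_read()]
#' (memoised over identical read sequences). Every read ends up exactly once
#' in the assignments (possibly with several equally good hit positions) or
#' in the unmapped set.
#'
#' @param reads named character vector of read sequences, or a data.frame
#'   with `read_id` and `sequence` columns (e.g. from [simulate_sirna()]).
#' @param locus a `reporter_locus`.
#' @param rnaseq_alignments alignment data.frame used to establish supported
#'   junctions; when `NULL`, the locus's annotated splice pairs are used.
#' @param flank junction-fragment flank (nt); must be >= longest read - 1.
#' @param length_filter inclusive read-length window retained for mapping.
#' @param min_support minimum split-read support for a junction.
#' @param min_match tier-4 minimum matched length.
#' @return list: `assignments` (alignment data.frame with `tier`,
#'   `mismatches`, `n_hits`, `read_len`), `unmapped` (read ids),
#'   `tier_tally` (named counts over tiers 1-4), `library_size` (reads
#'   passing the length filter), `n_input`.
#' @export
map_library <- function(reads, locus, rnaseq_alignments = NULL,
                        flank = 29L, length_filter = c(18L, 30L),
                        min_support = 1L, min_match = 14L) {
  if (is.data.frame(reads)) {
    reads <- stats::setNames(reads$sequence, reads$read_id)
  }
  n_input <- length(reads)
  lens <- nchar(reads)
  keep <- lens >= length_filter[1] & lens <= length_filter[2]
  reads <- reads[keep]
  if (length(reads) && flank < max(nchar(reads)) - 1L) {
    sr_stop("flank must be at least the longest read length minus one",
            "sr_precondition_error")
  }

  if (is.null(rnaseq_alignments)) {
    junctions <- locus$splice_pairs[, c("donor", "acceptor")]
  } else {
    junctions <- junctions_from_alignments(rnaseq_alignments, min_support)
  }
  fragments <- build_junction_fragments(locus, junctions, flank)
  subjects <- compile_subjects(locus, fragments)

  uniq <- unique(unname(reads))
  cache <- lapply(uniq, assign_read, locus = locus, fragments = fragments,
                  min_match = min_match, subjects = subjects)
  names(cache) <- uniq

  per_read <- lapply(seq_along(reads), function(i) {
    h <- cache[[reads[[i]]]]
    if (nrow(h) == 0) return(NULL)
    cbind(read_id = names(reads)[i], h, read_len = nchar(reads[[i]]),
          stringsAsFactors = FALSE)
  })
  mapped <- !vapply(per_read, is.null, logical(1))
  assignments <- if (any(mapped)) {
    do.call(rbind, per_read[mapped])
  } else {
    data.frame(read_id = character(0), tier = integer(0),
               strand = character(0), start1 = integer(0), end1 = integer(0),
               start2 = integer(0), end2 = integer(0),
               mismatches = integer(0), n_hits = integer(0),
               read_len = integer(0), stringsAsFactors = FALSE)
  }
  rownames(assignments) <- NULL
  tier_of_read <- vapply(per_read[mapped], function(x) x$tier[1], integer(1))
  tally <- stats::setNames(tabulate(tier_of_read, nbins = 4L),
                           paste0("tier", 1:4))
  list(assignments = assignments,
       unmapped = names(reads)[!mapped],
       tier_tally = tally,
       library_size = length(reads),
       n_input = n_input)
}
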