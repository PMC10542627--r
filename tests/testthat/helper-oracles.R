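# Independent, deliberately naive oracles used to cross-check the
# implementation. These share no code with the package internals: character
# vectors and explicit loops only.

oracle_revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(x, "")[[1]]]), collapse = "")
}

# mismatch count of `read` placed at 0-based `pos` on `subject`; N always
# mismatches
oracle_mm_at <- function(read, subject, pos) {
  r <- strsplit(read, "")[[1]]
  s <- strsplit(substr(subject, pos + 1, pos + nchar(read)), "")[[1]]
  sum(r != s | r == "N" | s == "N")
}

# all 0-based placements of `read` on `subject` with at most `max_mm`
# substitutions (position loop over pre-split character vectors)
oracle_scan <- function(read, subject, max_mm = 0) {
  r <- strsplit(read, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  k <- length(r)
  L <- length(s)
  if (L < k) return(integer(0))
  pos <- 0:(L - k)
  mm <- vapply(pos, function(p) {
    w <- s[(p + 1):(p + k)]
    sum(w != r | r == "N" | w == "N")
  }, numeric(1))
  pos[mm <= max_mm]
}

# Does any hit exist at the given cascade tier? (tiers 1-3; used to verify
# minimality of assigned tiers)
oracle_tier_has_hit <- function(read, locus, fragments, tier) {
  tx <- substr(locus$sequence, locus$tss + 1, nchar(locus$sequence))
  rc <- oracle_revcomp(read)
  both <- function(subject, mm) {
    length(oracle_scan(read, subject, mm)) + length(oracle_scan(rc, subject, mm))
  }
  frag_hits <- function(mm) {
    n <- 0
    for (fr in fragments) {
      for (r in c(read, rc)) {
        for (p in oracle_scan(r, fr$sequence, mm)) {
          if (p < fr$flank && p + nchar(r) > fr$flank) n <- n + 1
        }
      }
    }
    n
  }
  switch(tier,
         `1` = both(tx, 0) > 0,
         `2` = frag_hits(0) > 0,
         `3` = both(tx, 1) > 0 || frag_hits(1) > 0)
}

# Naive seed-and-extend mapper over the whole vector: exact 9-mer seeds,
# ungapped extension with at most one substitution. Returns the best score
# (matches) achievable, or 0.
oracle_seed_extend <- function(read, locus_seq, seed_len = 9, min_match = 14) {
  best <- 0
  for (r in c(read, oracle_revcomp(read))) {
    k <- nchar(r)
    for (i in 0:(k - seed_len)) {
      seed <- substr(r, i + 1, i + seed_len)
      for (p in oracle_scan(seed, locus_seq, 0)) {
        # extend the diagonal d = p - i over the full overlap
        d <- p - i
        lo <- max(0, -d)
        hi <- min(k, nchar(locus_seq) - d)
        rr <- strsplit(substr(r, lo + 1, hi), "")[[1]]
        ss <- strsplit(substr(locus_seq, d + lo + 1, d + hi), "")[[1]]
        mism <- which(rr != ss | rr == "N" | ss == "N")
        bounds <- c(0, mism, length(rr) + 1)
        for (j in seq_len(length(bounds) - 2)) {
          matches <- bounds[j + 2] - bounds[j] - 2
          if (matches >= min_match) best <- max(best, matches)
        }
        if (length(mism) == 0 && length(rr) >= min_match) {
          best <- max(best, length(rr))
        }
      }
    }
  }
  best
}

# Plain-R ORF oracle: scan every position for the start-selection rule, then
# translate codon by codon.
oracle_orf <- function(seq, std, cds_len) {
  stops <- c("TAA", "TAG", "TGA")
  start <- std
  i <- std %% 3
  while (i < std) {
    if (substr(seq, i + 1, i + 3) == "ATG") { start <- i; break }
    i <- i + 3
  }
  pos <- start
  first_stop <- NA
  while (pos + 3 <= std + cds_len) {
    if (substr(seq, pos + 1, pos + 3) %in% stops) { first_stop <- pos; break }
    pos <- pos + 3
  }
  translatable <- is.na(first_stop) || first_stop == std + cds_len - 3
  list(start_used = start, stop_position = first_stop,
       translatable = translatable,
       n_terminal_extension = (std - start) / 3)
}

# Small alignment-frame builders for constructed toy cases
toy_contig <- function(n, start, end, strand = "+") {
  alignment_frame(sprintf("c%03d", seq_len(n)), strand,
                  rep(start, n), rep(end, n))
}

toy_split <- function(n, s1, gap_start, gap_end, e2, strand = "+") {
  alignment_frame(sprintf("s%03d", seq_len(n)), strand,
                  rep(s1, n), rep(gap_start, n), rep(gap_end, n), rep(e2, n))
}

# default locus shared across tests (cheap to build, deterministic)
test_locus <- function(seed = 101) build_reporter_locus(default_config(seed = seed))
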