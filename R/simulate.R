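# Vectorised projection of mature-transcript intervals [s, e) onto locus
# blocks for a variant with at most one junction. Returns start1/end1/
# start2/end2 integer vectors (NA second block for contiguous projections).
project_intervals <- function(blocks, s, e) {
  n <- length(s)
  if (nrow(blocks) == 1L) {
    return(list(start1 = blocks[1, 1] + s, end1 = blocks[1, 1] + e,
                start2 = rep(NA_integer_, n), end2 = rep(NA_integer_, n)))
  }
  j <- blocks[1, 2] - blocks[1, 1]              # junction in mature coords
  b1s <- blocks[1, 1]; b2s <- blocks[2, 1]
  left <- e <= j
  right <- s >= j
  span <- !left & !right
  start1 <- ifelse(right, b2s + (s - j), b1s + s)
  end1 <- ifelse(left, b1s + e, ifelse(right, b2s + (e - j), blocks[1, 2]))
  start2 <- ifelse(span, b2s, NA_integer_)
  end2 <- ifelse(span, b2s + (e - j), NA_integer_)
  list(start1 = as.integer(start1), end1 = as.integer(end1),
       start2 = as.integer(start2), end2 = as.integer(end2))
}

# Inject substitution errors at a per-base rate into a character vector of
# sequences. Returns the mutated vector (assumes RNG state set by caller).
inject_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0) return(seqs)
  lens <- nchar(seqs)
  total <- sum(lens)
  hit <- which(runif(total) < error_rate)
  if (length(hit) == 0) return(seqs)
  ends <- cumsum(lens)
  read_of <- findInterval(hit - 1L, ends) + 1L
  pos_of <- hit - c(0L, ends)[read_of]          # 1-based within read
  for (k in seq_along(hit)) {
    i <- read_of[k]; p <- pos_of[k]
    old <- substr(seqs[i], p, p)
    new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    substr(seqs[i], p, p) <- new
  }
  seqs
}

#' Simulate paired-end RNA-seq alignments over the reporter
#'
#' Draws fragments from the three splice variants according to
#' `cfg$variant_mix`, with Gaussian fragment lengths and uniform fragment
#' placement along the chosen mature transcript. Both mates are emitted as
#' alignment rows with split blocks across splice junctions; truth labels
#' (source variant, mate, pair) are retained. Substitution errors are
#' injected at `cfg$error_rate` when sequences are materialised.
#'
#' @param locus a `reporter_locus`.
#' @param cfg a `sim_config`; depth is `cfg$n_rnaseq_read_pairs`.
#' @param sequences materialise read sequences? Disabling this skips all
#'   string work and is used for large Monte Carlo studies where only the
#'   alignment geometry matters.
#' @return alignment data.frame with columns `read_id`, `strand`,
#'   `start1..end2`, `variant`, `mate`, `pair_id` (and `sequence` when
#'   requested).
#' @export
simulate_rnaseq <- function(locus, cfg = locus$config, sequences = TRUE) {
  validate_config(cfg)
  n <- cfg$n_rnaseq_read_pairs
  rl <- cfg$rnaseq_read_len
  labels <- c("unspliced", "gu_ag", "au_ac")
  blocks <- lapply(labels, variant_blocks, locus = locus)
  names(blocks) <- labels
  matures <- vapply(labels, mature_sequence, character(1), locus = locus)
  mlen <- nchar(matures)
  if (rl > min(mlen)) {
    sr_stop("rnaseq_read_len exceeds the shortest mature transcript",
            "sr_config_error")
  }
  empty <- alignment_frame(character(0), character(0), integer(0), integer(0),
                           variant = character(0), mate = integer(0),
                           pair_id = integer(0))
  if (n == 0) {
    if (sequences) empty$sequence <- character(0)
    return(empty)
  }

  withr::with_seed(cfg$seed + 1L, {
    vidx <- sample.int(3L, n, replace = TRUE, prob = cfg$variant_mix)
    vlen <- mlen[vidx]
    flen <- pmin(pmax(round(rnorm(n, cfg$fragment_len_mean,
                                  cfg$fragment_len_sd)), rl), vlen)
    fstart <- floor(runif(n) * (vlen - flen + 1))
    s1 <- as.integer(fstart); e1 <- as.integer(fstart + rl)
    s2 <- as.integer(fstart + flen - rl); e2 <- as.integer(fstart + flen)

    out <- vector("list", 3L)
    for (v in 1:3) {
      sel <- which(vidx == v)
      if (!length(sel)) next
      p1 <- project_intervals(blocks[[v]], s1[sel], e1[sel])
      p2 <- project_intervals(blocks[[v]], s2[sel], e2[sel])
      df <- data.frame(
        read_id = c(sprintf("rna%06d/1", sel), sprintf("rna%06d/2", sel)),
        strand = rep(c("+", "-"), each = length(sel)),
        start1 = c(p1$start1, p2$start1), end1 = c(p1$end1, p2$end1),
        start2 = c(p1$start2, p2$start2), end2 = c(p1$end2, p2$end2),
        variant = labels[v],
        mate = rep(c(1L, 2L), each = length(sel)),
        pair_id = c(sel, sel),
        m_start = c(s1[sel], s2[sel]), m_end = c(e1[sel], e2[sel]),
        stringsAsFactors = FALSE)
      if (sequences) {
        raw1 <- substring(matures[v], s1[sel] + 1L, e1[sel])
        raw2 <- revcomp(substring(matures[v], s2[sel] + 1L, e2[sel]))
        df$sequence <- c(raw1, raw2)
      }
      out[[v]] <- df
    }
    ali <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    ali <- ali[order(ali$pair_id, ali$mate), , drop = FALSE]
    rownames(ali) <- NULL
    if (sequences) ali$sequence <- inject_errors(ali$sequence, cfg$error_rate)
    validate_alignments(ali, nchar(locus$sequence))
    ali
  })
}

#' Simulate a genotype-dependent small-RNA population
#'
#' Draws small-RNA reads as substrings (sense) or reverse complements
#' (antisense) of the two untranslatable transcripts (GU-AG product and
#' unspliced pre-mRNA) only; the translatable AU-AC variant is never a
#' source. Read lengths follow `size_mix` over 21/22/24 nt, source regions
#' follow `source_weights` (GFP CDS vs the upstream exon present only in the
#' untranslatable forms), and per-start sampling weight decays toward the
#' transcript 5' end as `exp(-gradient_strength * dist_from_3p / length)`,
#' emulating declining RDR6 processivity. Truth (origin variant, origin
#' interval in mature and locus coordinates, strand) is retained.
#'
#' @param locus a `reporter_locus`.
#' @param cfg a `sim_config`.
#' @param preset genotype preset name or override list (see
#'   [genotype_presets()]); applied on top of `cfg`.
#' @return data.frame with `read_id`, `sequence` (as sequenced), `length`,
#'   `strand`, `variant`, `m_start`, `m_end` (mature truth interval), and
#'   truth locus blocks `start1..end2`.
#' @export
simulate_sirna <- function(locus, cfg = locus$config, preset = "WT_T") {
  cfg <- apply_preset(cfg, preset)
  n <- cfg$n_sirna_reads
  empty <- data.frame(read_id = character(0), sequence = character(0),
                      length = integer(0), strand = character(0),
                      variant = character(0), m_start = integer(0),
                      m_end = integer(0), start1 = integer(0),
                      end1 = integer(0), start2 = integer(0),
                      end2 = integer(0), stringsAsFactors = FALSE)
  if (n == 0) return(empty)

  labels <- c("gu_ag", "unspliced")
  blocks <- lapply(labels, variant_blocks, locus = locus)
  matures <- vapply(labels, mature_sequence, character(1), locus = locus)
  mlen <- nchar(matures)

  # allowed start windows (mature coordinates), per variant x source region
  cds <- locus$regions$gfp_cds
  au <- locus$splice_pairs[locus$splice_pairs$site_class == "noncanonical_AU_AC", ]
  gu <- locus$splice_pairs[locus$splice_pairs$site_class == "canonical_GU_AG", ]
  win <- function(v, region, len) {
    bl <- blocks[[v]]
    if (region == "gfp_cds") {
      lo <- locus_to_mature(bl, cds[1])
      hi <- lo + (cds[2] - cds[1]) - len          # stay within the CDS
    } else {
      lo <- locus_to_mature(bl, au$donor)          # upstream exon: AU donor..
      hi <- locus_to_mature(bl, gu$donor - 1L)     # ..GU donor (may run past)
      hi <- min(hi, mlen[v] - len)
    }
    c(lo, hi)
  }

  withr::with_seed(cfg$seed + 2L, {
    sizes <- c(21L, 22L, 24L)
    len <- sizes[sample.int(3L, n, replace = TRUE, prob = cfg$size_mix)]
    strand <- ifelse(runif(n) < cfg$antisense_fraction, "-", "+")
    region <- c("gfp_cds", "upstream_exon")[
      sample.int(2L, n, replace = TRUE, prob = cfg$source_weights)]
    vidx <- sample.int(2L, n, replace = TRUE,
                       prob = cfg$source_variant_weights)

    m_start <- integer(n)
    for (v in 1:2) for (rg in c("gfp_cds", "upstream_exon")) {
      for (l in sizes) {
        sel <- which(vidx == v & region == rg & len == l)
        if (!length(sel)) next
        w <- win(v, rg, l)
        starts <- w[1]:w[2]
        g <- cfg$gradient_strength
        wt <- exp(-g * (mlen[v] - starts) / mlen[v])
        m_start[sel] <- sample(starts, length(sel), replace = TRUE, prob = wt)
      }
    }
    m_end <- m_start + len

    seqs <- character(n)
    p <- list(start1 = integer(n), end1 = integer(n),
              start2 = rep(NA_integer_, n), end2 = rep(NA_integer_, n))
    for (v in 1:2) {
      sel <- which(vidx == v)
      if (!length(sel)) next
      seqs[sel] <- substring(matures[v], m_start[sel] + 1L, m_end[sel])
      pj <- project_intervals(blocks[[v]], m_start[sel], m_end[sel])
      p$start1[sel] <- pj$start1; p$end1[sel] <- pj$end1
      p$start2[sel] <- pj$start2; p$end2[sel] <- pj$end2
    }
    neg <- strand == "-"
    seqs[neg] <- revcomp(seqs[neg])
    seqs <- inject_errors(seqs, cfg$error_rate)

    data.frame(read_id = sprintf("sirna%06d", seq_len(n)),
               sequence = seqs, length = len, strand = strand,
               variant = labels[vidx], m_start = m_start, m_end = m_end,
               start1 = p$start1, end1 = p$end1,
               start2 = p$start2, end2 = p$end2,
               stringsAsFactors = FALSE)
  })
}
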