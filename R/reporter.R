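#' Default simulation configuration
#'
#' Returns the configuration that drives the synthetic reporter locus and the
#' read simulators. The defaults are the study conditions: region lengths of
#' 1277 bp (enhancer), 91 bp (minimal promoter) and 720 bp (GFP CDS) for a
#' 2088 bp expression region, three splice variants of which only the
#' noncanonical AU-AC product is translatable, and a wild-type-like small-RNA
#' population (21-nt modal size class, both strands, CDS-biased with sparse
#' upstream coverage). Genotype presets (see [genotype_presets()]) override
#' individual fields.
#'
#' @param seed integer seed; fully determines every simulated output.
#' @param ... named overrides for any configuration field.
#' @return a list of class `sim_config`. Fields:
#' \describe{
#'   \item{n_rnaseq_read_pairs, rnaseq_read_len}{RNA-seq depth (fragments) and
#'     mate length in nt.}
#'   \item{fragment_len_mean, fragment_len_sd}{RNA-seq fragment-length model.}
#'   \item{variant_mix}{probabilities over (unspliced, gu_ag, au_ac).}
#'   \item{n_sirna_reads, size_mix, antisense_fraction}{small-RNA depth,
#'     probabilities over lengths (21, 22, 24) nt, and antisense proportion
#'     (0.5: both arms of a dsRNA precursor are diced).}
#'   \item{source_weights}{probabilities over siRNA source regions
#'     (gfp_cds, upstream_exon).}
#'   \item{source_variant_weights}{which untranslatable transcript a siRNA
#'     derives from (gu_ag, unspliced); the translatable AU-AC variant is
#'     never a source.}
#'   \item{gradient_strength}{unitless decay of per-start sampling weight
#'     toward the transcript 5' end, modelling declining RDR6 processivity.}
#'   \item{error_rate}{per-base substitution probability.}
#'   \item{enhancer_len, promoter_len, cds_len}{region lengths in bp;
#'     configurable for stress tests, defaults are the reporter architecture.}
#' }
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_rnaseq_read_pairs = 2000L,
    rnaseq_read_len = 75L,
    fragment_len_mean = 180,
    fragment_len_sd = 20,
    variant_mix = c(unspliced = 0.25, gu_ag = 0.45, au_ac = 0.30),
    n_sirna_reads = 10000L,
    size_mix = c(`21` = 0.75, `22` = 0.15, `24` = 0.10),
    antisense_fraction = 0.5,
    source_weights = c(gfp_cds = 0.9, upstream_exon = 0.1),
    source_variant_weights = c(gu_ag = 0.85, unspliced = 0.15),
    gradient_strength = 2,
    error_rate = 0.001,
    enhancer_len = 1277L,
    promoter_len = 91L,
    cds_len = 720L,
    total_len = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    sr_stop(paste("unknown config fields:", paste(unknown, collapse = ", ")),
            "sr_config_error")
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' @param cfg a `sim_config` list.
#' @return `cfg`, invisibly; signals a condition of class `sr_config_error`
#'   on any violated invariant.
#' @export
validate_config <- function(cfg) {
  check_prob(cfg$variant_mix, "variant_mix")
  check_prob(cfg$size_mix, "size_mix")
  check_prob(cfg$source_weights, "source_weights")
  check_prob(cfg$source_variant_weights, "source_variant_weights")
  if (cfg$n_rnaseq_read_pairs < 0 || cfg$n_sirna_reads < 0) {
    sr_stop("read counts must be >= 0", "sr_config_error")
  }
  if (cfg$antisense_fraction < 0 || cfg$antisense_fraction > 1 ||
      cfg$error_rate < 0 || cfg$error_rate > 1) {
    sr_stop("antisense_fraction and error_rate must lie in [0, 1]",
            "sr_config_error")
  }
  if (cfg$gradient_strength < 0) {
    sr_stop("gradient_strength must be >= 0", "sr_config_error")
  }
  if (cfg$cds_len %% 3L != 0L) {
    sr_stop("gfp_cds length must be divisible by 3 (reading frame)",
            "sr_config_error")
  }
  if (cfg$enhancer_len < 600L || cfg$promoter_len < 30L || cfg$cds_len < 60L) {
    sr_stop("region lengths below structural minima (enhancer >= 600, promoter >= 30, cds >= 60)",
            "sr_config_error")
  }
  if ((cfg$enhancer_len + cfg$promoter_len) %% 3L != 0L) {
    sr_stop("enhancer + promoter length must be divisible by 3 so the upstream ATG can be in frame",
            "sr_config_error")
  }
  expect_total <- cfg$enhancer_len + cfg$promoter_len + cfg$cds_len
  if (!is.null(cfg$total_len) && cfg$total_len != expect_total) {
    sr_stop(sprintf("total_len (%d) contradicts region lengths (sum %d)",
                    cfg$total_len, expect_total),
            "sr_config_error")
  }
  invisible(cfg)
}

#' Genotype presets for the small-RNA simulator
#'
#' Named configuration overrides reproducing the qualitative siRNA phenotypes
#' of the genotypes studied with this reporter: loss of RDR6 eliminates all
#' reporter siRNAs; loss of DCL4 shifts production to DCL2-dependent 22-nt
#' siRNAs and raises their abundance; the cwc16a splicing mutant produces
#' almost exclusively the translatable AU-AC transcript and next to no
#' siRNAs; coi1 zch1 accumulates elevated 21-nt siRNAs.
#'
#' @return named list of override lists, one per genotype.
#' @export
genotype_presets <- function() {
  wt_mix <- c(unspliced = 0.25, gu_ag = 0.45, au_ac = 0.30)
  coi1_mix <- c(unspliced = 0.20, gu_ag = 0.38, au_ac = 0.42)
  cwc_mix <- c(unspliced = 0.05, gu_ag = 0.05, au_ac = 0.90)
  mix21 <- c(`21` = 0.75, `22` = 0.15, `24` = 0.10)
  mix22 <- c(`21` = 0.12, `22` = 0.78, `24` = 0.10)
  mix_zch <- c(`21` = 0.85, `22` = 0.08, `24` = 0.07)
  list(
    WT_T       = list(),
    coi1       = list(variant_mix = coi1_mix, n_sirna_reads = 13000L),
    rdr6       = list(n_sirna_reads = 0L),
    coi1_rdr6  = list(variant_mix = coi1_mix, n_sirna_reads = 0L),
    dcl4       = list(size_mix = mix22, n_sirna_reads = 20000L),
    coi1_dcl4  = list(variant_mix = coi1_mix, size_mix = mix22,
                      n_sirna_reads = 20000L),
    cwc16a     = list(variant_mix = cwc_mix, n_sirna_reads = 20L),
    cwc16a_dcl4 = list(variant_mix = cwc_mix, size_mix = mix22,
                       n_sirna_reads = 18000L),
    coi1_zch1  = list(variant_mix = coi1_mix, size_mix = mix_zch,
                      n_sirna_reads = 30000L)
  )
}

#' Apply a genotype preset to a configuration
#'
#' @param cfg base `sim_config`.
#' @param preset preset name (see [genotype_presets()]) or an override list.
#' @return the modified, validated `sim_config`.
#' @export
apply_preset <- function(cfg, preset) {
  if (is.character(preset)) {
    presets <- genotype_presets()
    if (!preset %in% names(presets)) {
      sr_stop(sprintf("unknown genotype preset '%s'", preset), "sr_config_error")
    }
    preset <- presets[[preset]]
  }
  cfg[names(preset)] <- preset
  validate_config(cfg)
  cfg
}

# Fixed structural anchors of the locus, derived from region lengths.
locus_anchors <- function(cfg) {
  E <- as.integer(cfg$enhancer_len)
  P <- as.integer(cfg$promoter_len)
  C <- as.integer(cfg$cds_len)
  tss <- 100L
  list(
    E = E, P = P, C = C, L = E + P + C,
    tss = tss,
    exon1_end = tss + 60L,
    au_donor = tss + 60L,
    gu_donor = 400L,
    gu_acceptor = E - 177L,
    au_acceptor = E + P - 27L,
    standard_atg = E + P,
    upstream_atg = tss + 6L
  )
}

#' Build the synthetic reporter locus
#'
#' Deterministically constructs a reporter sequence with the splicing
#' architecture of the GFP reporter transgene: transcription initiates at a
#' cryptic start (`tss`) inside the enhancer's short tandem repeats; the
#' transcript can be spliced at a canonical GU-AG pair nested inside a larger
#' noncanonical AU-AC pair, or remain unspliced. In-frame stop codons are
#' planted so that the unspliced and GU-AG mature transcripts are
#' untranslatable, while the AU-AC mature transcript carries a clean open
#' reading frame from an upstream in-frame ATG (81 nt, i.e. 27 codons, before
#' the annotated-but-unused standard GFP start) through the CDS end.
#' Sequence outside the fixed motifs is pseudo-random, fully determined by
#' `cfg$seed`.
#'
#' @param cfg a `sim_config`, see [default_config()].
#' @return an object of class `reporter_locus`: list with `name`, `sequence`,
#'   `regions` (0-based half-open intervals), `tss`, `splice_pairs`
#'   (data.frame: donor, acceptor, site_class), `upstream_atg`,
#'   `standard_atg`, and the generating `config`.
#' @export
build_reporter_locus <- function(cfg = default_config()) {
  validate_config(cfg)
  a <- locus_anchors(cfg)

  seq <- withr::with_seed(cfg$seed, {
    s <- strsplit(random_bases(a$L), "", fixed = TRUE)[[1]]

    put <- function(start0, str) {
      s[(start0 + 1L):(start0 + nchar(str))] <<- strsplit(str, "", fixed = TRUE)[[1]]
    }

    # three tandem repeats at the enhancer 5' end (house the cryptic promoter)
    unit <- random_bases(22L)
    put(20L, paste(rep(unit, 3L), collapse = ""))

    # first-exon head: no ATG at AU-AC mature offsets 0 and 3
    put(a$tss, "CACCTC")
    # upstream in-frame ATG + first-exon codons, stop-free in the AU-AC frame
    put(a$upstream_atg, paste0("ATG", random_codons(17L)))

    # decoy start for the unspliced standard-start frame ("CATGC" placement is
    # stop-free in the AU-AC frame wherever the frame constraint puts it)
    offs_std_unspliced <- a$standard_atg - a$tss      # mature offset, unspliced
    q_u <- a$tss + 18L
    while ((offs_std_unspliced - (q_u - a$tss)) %% 3L != 0L) q_u <- q_u + 1L
    put(q_u - 1L, "CATGC")

    # AU-AC donor
    put(a$au_donor, "AT")

    # decoy start + stop for the GU-AG standard-start frame, inside the exon
    # present in GU-AG/unspliced but absent from AU-AC
    offs_std_gu <- (a$gu_donor - a$tss) + (a$standard_atg - a$gu_acceptor)
    q_g <- 219L
    while ((offs_std_gu - (q_g - a$tss)) %% 3L != 0L) q_g <- q_g + 1L
    put(q_g, "ATG")
    put(q_g + 9L, "TAA")
    # stop in the upstream-ATG frame (shared by GU-AG and unspliced matures)
    r1 <- q_g + 14L
    while ((r1 - a$upstream_atg) %% 3L != 0L) r1 <- r1 + 1L
    put(r1, "TAA")

    # GU-AG donor, then a stop in the unspliced decoy frame inside the
    # unspliced-only central region
    put(a$gu_donor, "GT")
    r2 <- a$gu_donor + 2L
    while ((r2 - q_u) %% 3L != 0L) r2 <- r2 + 1L
    put(r2, "TAA")

    # acceptors
    put(a$gu_acceptor - 2L, "AG")
    put(a$au_acceptor - 2L, "AC")

    # 27-nt N-terminal extension (9 codons, stop-free in the AU-AC frame)
    put(a$au_acceptor, random_codons(9L))

    # GFP CDS: standard ATG, stop-free body, terminal stop
    put(a$standard_atg, paste0("ATG", random_codons(a$C %/% 3L - 2L), "TAA"))

    paste(s, collapse = "")
  })

  locus <- structure(list(
    name = "synthetic_reporter",
    sequence = seq,
    regions = list(
      enhancer = c(0L, a$E),
      minimal_promoter = c(a$E, a$E + a$P),
      gfp_cds = c(a$standard_atg, a$L),
      upstream_exon1 = c(a$tss, a$exon1_end),
      intron_gu_ag = c(a$gu_donor, a$gu_acceptor),
      intron_au_ac_span = c(a$au_donor, a$au_acceptor)
    ),
    tss = a$tss,
    splice_pairs = data.frame(
      donor = c(a$gu_donor, a$au_donor),
      acceptor = c(a$gu_acceptor, a$au_acceptor),
      site_class = c("canonical_GU_AG", "noncanonical_AU_AC"),
      stringsAsFactors = FALSE
    ),
    upstream_atg = a$upstream_atg,
    standard_atg = a$standard_atg,
    config = cfg
  ), class = "reporter_locus")

  validate_locus(locus)
  locus
}

#' Validate a reporter locus
#'
#' Checks the structural invariants: regions within the sequence, donor and
#' acceptor dinucleotides matching their declared splice-site class, and the
#' upstream ATG in frame with (and upstream of) the standard start in the
#' AU-AC mature coordinate system.
#'
#' @param locus a `reporter_locus`.
#' @return `locus`, invisibly; errors (class `sr_validation_error`) otherwise.
#' @export
validate_locus <- function(locus) {
  L <- nchar(locus$sequence)
  for (rn in names(locus$regions)) {
    r <- locus$regions[[rn]]
    check_intervals(r[1], r[2], L, paste("region", rn))
  }
  sp <- locus$splice_pairs
  if (any(sp$donor >= sp$acceptor)) {
    sr_stop("splice pair with donor >= acceptor", "sr_validation_error")
  }
  donor_di <- substr0(locus$sequence, sp$donor, sp$donor + 2L)
  acc_di <- substr0(locus$sequence, sp$acceptor - 2L, sp$acceptor)
  want_d <- ifelse(sp$site_class == "canonical_GU_AG", "GT", "AT")
  want_a <- ifelse(sp$site_class == "canonical_GU_AG", "AG", "AC")
  if (any(donor_di != want_d) || any(acc_di != want_a)) {
    sr_stop("splice-site dinucleotides do not match their declared class",
            "sr_validation_error")
  }
  if (locus$upstream_atg >= locus$standard_atg) {
    sr_stop("upstream ATG must precede the standard ATG", "sr_validation_error")
  }
  # in-frame in AU-AC mature coordinates
  bl <- variant_blocks(locus, "au_ac")
  d <- locus_to_mature(bl, locus$standard_atg) -
    locus_to_mature(bl, locus$upstream_atg)
  if (d %% 3L != 0L) {
    sr_stop("upstream ATG out of frame with standard start in AU-AC mature coordinates",
            "sr_validation_error")
  }
  invisible(locus)
}

#' @export
print.reporter_locus <- function(x, ...) {
  cat(sprintf("<reporter_locus '%s'> %d bp\n", x$name, nchar(x$sequence)))
  for (rn in names(x$regions)) {
    r <- x$regions[[rn]]
    cat(sprintf("  %-18s [%5d, %5d)  %4d bp\n", rn, r[1], r[2], r[2] - r[1]))
  }
  cat(sprintf("  tss %d; upstream ATG %d; standard ATG %d\n",
              x$tss, x$upstream_atg, x$standard_atg))
  invisible(x)
}

#' Exon blocks of one splice variant
#'
#' @param locus a `reporter_locus`.
#' @param label one of "unspliced", "gu_ag", "au_ac".
#' @return matrix of 0-based half-open `start`/`end` intervals on the locus.
#' @export
variant_blocks <- function(locus, label) {
  L <- nchar(locus$sequence)
  sp <- locus$splice_pairs
  gu <- sp[sp$site_class == "canonical_GU_AG", ]
  au <- sp[sp$site_class == "noncanonical_AU_AC", ]
  switch(label,
    unspliced = matrix(c(locus$tss, L), ncol = 2,
                       dimnames = list(NULL, c("start", "end"))),
    gu_ag = matrix(c(locus$tss, gu$donor, gu$acceptor, L), ncol = 2,
                   byrow = TRUE, dimnames = list(NULL, c("start", "end"))),
    au_ac = matrix(c(locus$tss, au$donor, au$acceptor, L), ncol = 2,
                   byrow = TRUE, dimnames = list(NULL, c("start", "end"))),
    sr_stop(sprintf("unknown variant label '%s'", label), "sr_validation_error")
  )
}

#' Mature sequence of a splice variant
#'
#' Concatenation of the variant's exon-block sequences.
#'
#' @inheritParams variant_blocks
#' @return character scalar.
#' @export
mature_sequence <- function(locus, label) {
  bl <- variant_blocks(locus, label)
  paste(substr0(locus$sequence, bl[, 1], bl[, 2]), collapse = "")
}

#' Map a locus position to mature-transcript coordinates
#'
#' @param blocks exon-block matrix from [variant_blocks()].
#' @param pos 0-based locus position; must fall inside an exon block.
#' @return 0-based mature-transcript position.
#' @export
locus_to_mature <- function(blocks, pos) {
  off <- 0L
  for (i in seq_len(nrow(blocks))) {
    if (pos >= blocks[i, 1] && pos < blocks[i, 2]) {
      return(off + (pos - blocks[i, 1]))
    }
    off <- off + (blocks[i, 2] - blocks[i, 1])
  }
  sr_stop(sprintf("locus position %d not exonic in this variant", pos),
          "sr_validation_error")
}

#' Project a mature-coordinate interval back onto locus blocks
#'
#' @param blocks exon-block matrix from [variant_blocks()].
#' @param s,e 0-based half-open interval in mature-transcript coordinates.
#' @return matrix of 0-based half-open locus intervals (1 or 2 rows, since
#'   each variant has at most one junction).
#' @export
mature_to_locus_blocks <- function(blocks, s, e) {
  widths <- blocks[, 2] - blocks[, 1]
  cum <- cumsum(c(0L, widths))
  out <- NULL
  for (i in seq_len(nrow(blocks))) {
    bs <- max(s, cum[i])
    be <- min(e, cum[i + 1])
    if (bs < be) {
      out <- rbind(out, c(blocks[i, 1] + (bs - cum[i]),
                          blocks[i, 1] + (be - cum[i])))
    }
  }
  colnames(out) <- c("start", "end")
  out
}

#' The contiguous (pre-mRNA) reporter transcript
#'
#' The transcript anticipated from the construct design: contiguous sequence
#' from the cryptic transcription start to the locus end. This is the tier-1
#' mapping reference of the prioritized small-RNA cascade.
#'
#' @param locus a `reporter_locus`.
#' @return list with `sequence` and its locus `offset` (0-based).
#' @export
canonical_transcript <- function(locus) {
  list(sequence = substr0(locus$sequence, locus$tss, nchar(locus$sequence)),
       offset = locus$tss)
}

#' Enumerate the splice variants of the reporter
#'
#' Returns the three detectable polyadenylated transcripts: unspliced
#' pre-mRNA, the canonical GU-AG product, and the noncanonical AU-AC product.
#' Translatability is established by [orf_scan()] on each mature sequence;
#' by construction exactly the AU-AC variant is translatable.
#'
#' @param locus a `reporter_locus`.
#' @return named list of three `splice_variant` objects with fields `label`,
#'   `exon_blocks`, `mature_sequence`, `translatable`, `orf`.
#' @export
enumerate_splice_variants <- function(locus) {
  classes <- locus$splice_pairs$site_class
  if (!all(c("canonical_GU_AG", "noncanonical_AU_AC") %in% classes)) {
    sr_stop("locus must carry one canonical GU-AG and one noncanonical AU-AC splice pair",
            "sr_structural_error")
  }
  cds_len <- locus$regions$gfp_cds[2] - locus$regions$gfp_cds[1]
  out <- lapply(c("unspliced", "gu_ag", "au_ac"), function(label) {
    bl <- variant_blocks(locus, label)
    mat <- mature_sequence(locus, label)
    std <- locus_to_mature(bl, locus$standard_atg)
    orf <- orf_scan(mat, std, cds_length = cds_len)
    structure(list(label = label, exon_blocks = bl, mature_sequence = mat,
                   translatable = orf$translatable, orf = orf),
              class = "splice_variant")
  })
  names(out) <- c("unspliced", "gu_ag", "au_ac")
  n_tr <- sum(vapply(out, `[[`, logical(1), "translatable"))
  if (n_tr != 1L) {
    sr_stop(sprintf("expected exactly one translatable variant, found %d", n_tr),
            "sr_structural_error")
  }
  out
}
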