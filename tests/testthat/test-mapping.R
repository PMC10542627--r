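test_that("junction fragments concatenate the flanks with one coordinate jump", {
  loc <- test_locus()
  au <- loc$splice_pairs[loc$splice_pairs$site_class == "noncanonical_AU_AC", ]
  fr <- build_junction_fragments(loc, au, flank = 29L)[[1]]
  expect_equal(nchar(fr$sequence), 58)
  expect_identical(fr$sequence,
                   paste0(substr(loc$sequence, au$donor - 29 + 1, au$donor),
                          substr(loc$sequence, au$acceptor + 1, au$acceptor + 29)))
  expect_equal(fr$left_start, au$donor - 29)
  expect_error(build_junction_fragments(
    loc, data.frame(donor = 10L, acceptor = 5000L), 29L),
    class = "sr_validation_error")
})

test_that("only RNA-seq-supported junctions become fragments", {
  loc <- test_locus()
  au <- loc$splice_pairs[loc$splice_pairs$site_class == "noncanonical_AU_AC", ]
  # RNA-seq evidence for the AU-AC junction only
  rna <- toy_split(3, au$donor - 40, au$donor, au$acceptor, au$acceptor + 40)
  j <- junctions_from_alignments(rna)
  expect_equal(nrow(j), 1)
  expect_equal(c(j$donor, j$acceptor), c(au$donor, au$acceptor))
  # an error-free GU-AG junction read then has no tier-2 target
  gum <- mature_sequence(loc, "gu_ag")
  gu <- loc$splice_pairs[loc$splice_pairs$site_class == "canonical_GU_AG", ]
  jp <- locus_to_mature(variant_blocks(loc, "gu_ag"), gu$acceptor)
  read <- substr(gum, jp - 10, jp + 10)          # 10 nt left, 11 nt right
  res <- map_library(c(gu_read = read), loc, rna)
  expect_false(any(res$assignments$tier == 2))
})

test_that("the length-filter precondition on the flank is enforced", {
  loc <- test_locus()
  expect_error(map_library(c(r = paste(rep("A", 30), collapse = "")),
                           loc, NULL, flank = 20L),
               class = "sr_precondition_error")
})

test_that("tier assignment follows the worked examples", {
  loc <- test_locus()
  fragments <- build_junction_fragments(loc, loc$splice_pairs, 29L)
  cds <- loc$regions$gfp_cds

  # exact CDS 21-mer: tier 1, one block, sense
  read <- substr(loc$sequence, cds[1] + 301, cds[1] + 321)
  h <- assign_read(read, loc, fragments)
  expect_equal(unique(h$tier), 1)
  expect_true(any(h$strand == "+" & h$start1 == cds[1] + 300 &
                  h$end1 == cds[1] + 321 & h$mismatches == 0))

  # its reverse complement: tier 1, antisense
  h2 <- assign_read(oracle_revcomp(read), loc, fragments)
  expect_equal(unique(h2$tier), 1)
  expect_true(any(h2$strand == "-" & h2$start1 == cds[1] + 300))

  # 22-mer spanning the AU-AC junction, 11 nt each side: tier 2, two blocks
  au <- loc$splice_pairs[loc$splice_pairs$site_class == "noncanonical_AU_AC", ]
  aum <- mature_sequence(loc, "au_ac")
  j <- locus_to_mature(variant_blocks(loc, "au_ac"), au$acceptor)
  read3 <- substr(aum, j - 11 + 1, j + 11)
  h3 <- assign_read(read3, loc, fragments)
  expect_equal(unique(h3$tier), 2)
  expect_equal(h3$end1, au$donor)        # blocks abut donor and acceptor
  expect_equal(h3$start2, au$acceptor)
  expect_equal(h3$start1, au$donor - 11)
  expect_equal(h3$end2, au$acceptor + 11)

  # one substitution in a transcript read: tier 3 with 1 mismatch
  read4 <- read
  substr(read4, 11, 11) <- setdiff(c("A", "C", "G", "T"),
                                   substr(read4, 11, 11))[1]
  h4 <- assign_read(read4, loc, fragments)
  expect_equal(unique(h4$tier), 3)
  expect_equal(unique(h4$mismatches), 1)

  # reads with non-ACGTN characters are rejected
  expect_error(assign_read("ACGTX", loc), class = "sr_validation_error")
})

test_that("the tier-4 fallback finds partial matches of at least 14 nt", {
  loc <- test_locus()
  # enhancer sequence upstream of the transcription start: unreachable by
  # tiers 1-3, perfect on the vector
  read <- substr(loc$sequence, 51, 72)
  h <- assign_read(read, loc, list())
  expect_equal(unique(h$tier), 4)
  expect_true(any(h$start1 == 50 & h$mismatches == 0))
  # two N positions force the partial scan; matched segment must be >= 14
  read2 <- read
  substr(read2, 2, 2) <- "N"; substr(read2, 20, 20) <- "N"
  h2 <- assign_read(read2, loc, list())
  expect_equal(unique(h2$tier), 4)
  expect_true(all(h2$end1 - h2$start1 - h2$mismatches >= 14))
  # a read too corrupted for any 14-nt match stays unmapped
  h3 <- assign_read(paste(rep(c("A", "C"), 11), collapse = ""), loc, list())
  expect_equal(nrow(h3), 0)
})

test_that("tier-4 exhaustive scan dominates a seed-and-extend oracle", {
  cfg <- default_config(seed = 19, error_rate = 0, n_sirna_reads = 60L)
  loc <- build_reporter_locus(cfg)
  s <- simulate_sirna(loc, cfg, "WT_T")
  set.seed(42)
  for (i in seq_len(12)) {
    r <- s$sequence[i]
    for (p in sample(nchar(r), 2)) {             # 2 substitutions -> tier 4
      substr(r, p, p) <- setdiff(c("A", "C", "G", "T"), substr(r, p, p))[1]
    }
    h <- assign_read(r, loc, list())
    oracle_best <- oracle_seed_extend(r, loc$sequence)
    if (oracle_best == 0) {
      next                                        # oracle finds nothing
    }
    expect_gt(nrow(h), 0)
    expect_gte(max(h$end1 - h$start1 - h$mismatches), oracle_best)
  }
})

test_that("assigned tiers are minimal: no lower tier has a hit", {
  cfg <- default_config(seed = 23, error_rate = 0.02, n_sirna_reads = 200L)
  loc <- build_reporter_locus(cfg)
  rna <- simulate_rnaseq(loc, cfg)
  s <- simulate_sirna(loc, cfg, "WT_T")   # WT preset keeps the 200-read depth
  res <- map_library(s, loc, rna)
  junctions <- junctions_from_alignments(rna)
  fragments <- build_junction_fragments(loc, junctions, 29L)
  first_hit <- res$assignments[!duplicated(res$assignments$read_id), ]
  seqs <- stats::setNames(s$sequence, s$read_id)
  for (i in seq_len(nrow(first_hit))) {
    tier <- first_hit$tier[i]
    read <- seqs[[first_hit$read_id[i]]]
    for (lower in seq_len(tier - 1)) {
      if (lower > 3) break
      expect_false(oracle_tier_has_hit(read, loc, fragments, lower),
                   label = sprintf("read %s at tier %d has no tier-%d hit",
                                   first_hit$read_id[i], tier, lower))
    }
  }
  expect_equal(sum(res$tier_tally) + length(res$unmapped), res$library_size)
})

test_that("error-free libraries map at tiers 1-2, mutated ones at 3-4", {
  cfg <- default_config(seed = 29, error_rate = 0, n_sirna_reads = 400L)
  loc <- build_reporter_locus(cfg)
  rna <- simulate_rnaseq(loc, cfg)
  s <- simulate_sirna(loc, cfg, "WT_T")
  res <- map_library(s, loc, rna)
  expect_equal(length(res$unmapped), 0)
  expect_equal(sum(res$tier_tally[c("tier3", "tier4")]), 0)
  expect_gt(res$tier_tally[["tier1"]], 0)

  set.seed(7)
  mutated <- vapply(s$sequence, function(x) {
    p <- sample(nchar(x), 1)
    substr(x, p, p) <- setdiff(c("A", "C", "G", "T"), substr(x, p, p))[1]
    x
  }, character(1))
  res2 <- map_library(stats::setNames(mutated, s$read_id), loc, rna)
  expect_equal(length(res2$unmapped), 0)
  expect_equal(sum(res2$tier_tally[c("tier1", "tier2")]), 0)
})

test_that("truth-labelled junction reads project back to their truth blocks", {
  cfg <- default_config(seed = 37, error_rate = 0, n_sirna_reads = 2000L)
  loc <- build_reporter_locus(cfg)
  s <- simulate_sirna(loc, cfg, "WT_T")
  res <- map_library(s, loc, simulate_rnaseq(loc, cfg))
  a <- res$assignments[res$assignments$n_hits == 1, ]
  m <- merge(a, s, by = "read_id")
  expect_gt(sum(!is.na(m$start2.y)), 0)          # some junction reads present
  expect_true(all(m$start1.x == m$start1.y & m$end1.x == m$end1.y))
  both_na <- is.na(m$start2.x) & is.na(m$start2.y)
  expect_true(all(both_na | (m$start2.x == m$start2.y & m$end2.x == m$end2.y)))
})

test_that("an empty read set maps to empty outputs", {
  loc <- test_locus()
  res <- map_library(character(0), loc, NULL)
  expect_equal(nrow(res$assignments), 0)
  expect_equal(sum(res$tier_tally), 0)
  expect_equal(res$library_size, 0)
})
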