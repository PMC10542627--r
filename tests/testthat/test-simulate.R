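test_that("degenerate variant mixes behave as stated", {
  loc <- test_locus()
  cfg <- default_config(seed = 3, variant_mix = c(0, 0, 1), error_rate = 0,
                        n_rnaseq_read_pairs = 500L)
  a <- simulate_rnaseq(loc, cfg)
  au <- loc$splice_pairs[loc$splice_pairs$site_class == "noncanonical_AU_AC", ]
  split <- a[!is.na(a$start2), ]
  expect_gt(nrow(split), 0)
  expect_true(all(split$end1 == au$donor & split$start2 == au$acceptor))

  cfg0 <- default_config(seed = 3, n_rnaseq_read_pairs = 0L)
  expect_equal(nrow(simulate_rnaseq(loc, cfg0)), 0)

  expect_error(simulate_rnaseq(loc, default_config(rnaseq_read_len = 5000L)),
               class = "sr_config_error")
})

test_that("RNA-seq variant sampling recovers the mix within multinomial error", {
  loc <- test_locus()
  n <- 30000L
  cfg <- default_config(seed = 12, n_rnaseq_read_pairs = n,
                        variant_mix = c(1, 1, 1) / 3)
  a <- simulate_rnaseq(loc, cfg, sequences = FALSE)
  frac <- table(a$variant[a$mate == 1]) / n
  se <- sqrt((1 / 3) * (2 / 3) / n)
  expect_true(all(abs(frac - 1 / 3) < 3 * se))
})

test_that("simulated reads reconstruct exactly from their truth blocks", {
  cfg <- default_config(seed = 21, error_rate = 0, n_sirna_reads = 400L,
                        n_rnaseq_read_pairs = 200L)
  loc <- build_reporter_locus(cfg)
  rebuild <- function(df, i) {
    x <- substr(loc$sequence, df$start1[i] + 1, df$end1[i])
    if (!is.na(df$start2[i])) {
      x <- paste0(x, substr(loc$sequence, df$start2[i] + 1, df$end2[i]))
    }
    if (df$strand[i] == "-") x <- oracle_revcomp(x)
    x
  }
  s <- simulate_sirna(loc, cfg, "WT_T")
  for (i in seq_len(nrow(s))) expect_identical(rebuild(s, i), s$sequence[i])
  a <- simulate_rnaseq(loc, cfg)
  for (i in sample(nrow(a), 100)) expect_identical(rebuild(a, i), a$sequence[i])
})

test_that("siRNA genotype presets produce the published phenomenology", {
  loc <- test_locus()
  cfg <- default_config(seed = 5)
  expect_equal(nrow(simulate_sirna(loc, cfg, "rdr6")), 0)
  expect_equal(nrow(simulate_sirna(loc, cfg, "coi1_rdr6")), 0)
  d <- simulate_sirna(loc, cfg, "dcl4")
  expect_equal(as.integer(names(which.max(table(d$length)))), 22)
  z <- simulate_sirna(loc, cfg, "coi1_zch1")
  expect_equal(as.integer(names(which.max(table(z$length)))), 21)
  expect_gt(nrow(z), nrow(simulate_sirna(loc, cfg, "WT_T")))
})

test_that("siRNA length mixture is recovered within binomial error", {
  loc <- test_locus()
  n <- 8000L
  cfg <- default_config(seed = 8, n_sirna_reads = n)
  s <- simulate_sirna(loc, cfg, "WT_T")
  for (l in c("21", "22", "24")) {
    p <- cfg$size_mix[[l]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(s$length == as.integer(l)) - p), 3 * se)
  }
})

test_that("with no gradient, CDS start positions are uniform", {
  loc <- test_locus()
  cfg <- default_config(seed = 13, n_sirna_reads = 6000L,
                        gradient_strength = 0,
                        source_weights = c(gfp_cds = 1, upstream_exon = 0),
                        size_mix = c(`21` = 1, `22` = 0, `24` = 0),
                        error_rate = 0)
  s <- simulate_sirna(loc, cfg, "WT_T")
  # all starts inside the CDS on the locus
  cds <- loc$regions$gfp_cds
  expect_true(all(s$start1 >= cds[1] & s$end1 <= cds[2]))
  counts <- table(cut(s$start1, breaks = seq(cds[1], cds[2] - 20, length.out = 11)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("siRNAs are never drawn from AU-AC-exclusive sequence", {
  # the AU-AC junction context exists only in the translatable variant; with
  # no errors, no simulated siRNA may match it perfectly
  cfg <- default_config(seed = 31, error_rate = 0, n_sirna_reads = 3000L)
  loc <- build_reporter_locus(cfg)
  au <- loc$splice_pairs[loc$splice_pairs$site_class == "noncanonical_AU_AC", ]
  aum <- mature_sequence(loc, "au_ac")
  bl <- variant_blocks(loc, "au_ac")
  j <- locus_to_mature(bl, au$acceptor)          # junction point, mature coords
  s <- simulate_sirna(loc, cfg, "coi1")
  expect_true(all(s$variant %in% c("gu_ag", "unspliced")))
  # every k-mer of the AU-AC mature that straddles its junction is sequence
  # exclusive to that variant; no simulated read may equal one (either strand)
  junction_kmers <- unlist(lapply(unique(s$length), function(k) {
    starts <- (j - k + 1):(j - 1)
    substring(aum, starts + 1, starts + k)
  }))
  expect_false(any(s$sequence %in% junction_kmers))
  expect_false(any(vapply(unique(s$sequence), oracle_revcomp, character(1))
                   %in% junction_kmers))
})

test_that("a fixed seed makes simulation byte-identical", {
  loc <- test_locus()
  cfg <- default_config(seed = 77, n_sirna_reads = 300L,
                        n_rnaseq_read_pairs = 150L)
  expect_identical(simulate_sirna(loc, cfg, "coi1"),
                   simulate_sirna(loc, cfg, "coi1"))
  expect_identical(simulate_rnaseq(loc, cfg), simulate_rnaseq(loc, cfg))
})
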