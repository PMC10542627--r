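test_that("RPM values follow the definition", {
  a <- alignment_frame(sprintf("r%d", 1:5), "+", 100L + 0:4, 121L + 0:4,
                       n_hits = 1L, read_len = 21L)
  p <- size_strand_table(a, library_size = 1e6)
  expect_equal(p$rpm[p$length == 21 & p$strand == "+"], 5.0)
  expect_equal(sum(p$count), 5)

  a2 <- alignment_frame(sprintf("r%d", 1:21), "+", 100L + 0:20, 121L + 0:20,
                        n_hits = 1L, read_len = 21L)
  p2 <- size_strand_table(a2, library_size = 2e6)
  expect_equal(p2$rpm[p2$length == 21 & p2$strand == "+"], 10.5)

  expect_error(size_strand_table(a, library_size = 0),
               class = "sr_normalization_error")
})

test_that("rpm is invariant under joint scaling of counts and library size", {
  a <- alignment_frame(sprintf("r%d", 1:10), rep(c("+", "-"), 5),
                       100L + 0:9, 121L + 0:9, n_hits = 1L,
                       read_len = rep(c(21L, 24L), 5))
  p1 <- size_strand_table(a, library_size = 1000)
  a2 <- a[rep(seq_len(nrow(a)), 2), ]
  a2$read_id <- sprintf("r%d", seq_len(nrow(a2)))
  p2 <- size_strand_table(a2, library_size = 2000)
  expect_equal(p1$rpm, p2$rpm)
})

test_that("coverage adds fractional weight per hit over every aligned base", {
  loc <- test_locus()
  a <- alignment_frame("u", "+", 100L, 121L, n_hits = 1L, read_len = 21L)
  tr <- coverage_track(a, loc, library_size = 1e6)
  expect_equal(tr$values[101:121], rep(1, 21))
  expect_equal(sum(tr$values), 21)

  # the same read with two equally good hits: 0.5 at each location
  b <- alignment_frame(c("m", "m"), "+", c(100L, 400L), c(121L, 421L),
                       n_hits = 2L, read_len = 21L)
  tr2 <- coverage_track(b, loc, library_size = 1e6)
  expect_equal(tr2$values[101:121], rep(0.5, 21))
  expect_equal(tr2$values[401:421], rep(0.5, 21))

  expect_error(coverage_track(alignment_frame("x", "+", 0L, 5000L,
                                              n_hits = 1L, read_len = 21L),
                              loc, 1e6),
               class = "sr_validation_error")
})

test_that("coverage mass is conserved", {
  cfg <- default_config(seed = 41, n_sirna_reads = 1500L)
  loc <- build_reporter_locus(cfg)
  res <- map_library(simulate_sirna(loc, cfg, "WT_T"), loc,
                     simulate_rnaseq(loc, cfg))
  tr <- coverage_track(res$assignments, loc, res$library_size)
  expected <- sum((1 / res$assignments$n_hits) *
                  aligned_width(res$assignments)) * 1e6 / res$library_size
  expect_equal(sum(tr$values), expected, tolerance = 1e-6)
})

test_that("simulated genotypes are recovered in profile space", {
  cfg <- default_config(seed = 43, n_sirna_reads = 6000L)
  loc <- build_reporter_locus(cfg)
  rna <- simulate_rnaseq(loc, cfg)

  wt <- map_library(simulate_sirna(loc, cfg, "WT_T"), loc, rna)
  pwt <- size_strand_table(wt$assignments, wt$library_size, sample = "WT_T")
  expect_equal(modal_length(pwt), 21)

  d4 <- map_library(simulate_sirna(loc, cfg, "dcl4"), loc, rna)
  pd4 <- size_strand_table(d4$assignments, d4$library_size, sample = "dcl4")
  expect_equal(modal_length(pd4), 22)

  # rpm length proportions recover the size mix within 3 binomial SE
  n <- wt$library_size
  for (l in c(21, 22, 24)) {
    p <- cfg$size_mix[[as.character(l)]]
    got <- sum(pwt$rpm[pwt$length == l]) / sum(pwt$rpm)
    expect_lt(abs(got - p), 3 * sqrt(p * (1 - p) / n))
  }

  # CDS-biased sourcing shows up as higher CDS coverage
  tr <- coverage_track(wt$assignments, loc, wt$library_size)
  cds <- loc$regions$gfp_cds
  up <- c(loc$splice_pairs$donor[2], loc$splice_pairs$donor[1])  # AU..GU span
  expect_gt(mean(tr$values[(cds[1] + 1):cds[2]]),
            mean(tr$values[(up[1] + 1):up[2]]))
})

test_that("profile comparison flags zero denominators instead of inventing numbers", {
  a <- alignment_frame(sprintf("r%d", 1:4), "+", 100L + 0:3, 121L + 0:3,
                       n_hits = 1L, read_len = 21L)
  p <- size_strand_table(a, library_size = 1000)
  self <- compare_profiles(p, p)
  expect_true(all(self$ratio[self$flag == "ok"] == 1))
  expect_true(all(self$flag %in% c("ok", "undefined")))
  expect_equal(attr(self, "total_ratio"), 1)

  empty <- size_strand_table(a[0, ], library_size = 1000)
  cmp <- compare_profiles(empty, p)
  expect_equal(attr(cmp, "total_ratio"), 0)
  expect_equal(cmp$flag[cmp$length == 21 & cmp$strand == "+"], "ok")
  expect_true(all(cmp$flag[cmp$rpm_a == 0 & cmp$rpm_b == 0] == "undefined"))

  rev <- compare_profiles(p, empty)
  expect_equal(rev$flag[rev$length == 21 & rev$strand == "+"], "infinite")
  expect_true(is.na(rev$ratio[rev$length == 21 & rev$strand == "+"]))
})

test_that("an rdr6 library yields an all-zero profile relative to wild type", {
  cfg <- default_config(seed = 47, n_sirna_reads = 2000L)
  loc <- build_reporter_locus(cfg)
  rna <- simulate_rnaseq(loc, cfg)
  wt <- map_library(simulate_sirna(loc, cfg, "WT_T"), loc, rna)
  pwt <- size_strand_table(wt$assignments, wt$library_size)
  r6 <- simulate_sirna(loc, cfg, "rdr6")
  expect_equal(nrow(r6), 0)
  pr6 <- size_strand_table(
    alignment_frame(character(0), character(0), integer(0), integer(0),
                    n_hits = integer(0), read_len = integer(0)),
    library_size = wt$library_size)
  cmp <- compare_profiles(pr6, pwt)
  expect_equal(attr(cmp, "total_ratio"), 0)
})
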