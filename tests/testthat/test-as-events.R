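test_that("intron-retention counting matches the depth arithmetic", {
  intron <- c(100, 200)
  flanks <- list(c(0, 100), c(200, 300))
  # 5 x 21-nt reads inside the intron, 20 x 21-nt in each flanking exon
  aln <- rbind(toy_contig(5, 120L, 141L),
               toy_contig(20, 30L, 51L),
               toy_contig(20, 230L, 251L))
  expect_equal(count_ir(aln, intron, flanks, mode = "mean_depth"),
               c(signal = 1, background = 4))
  expect_equal(count_ir(aln, intron, flanks, mode = "read_count"),
               c(signal = 5, background = 40))

  # no intronic reads at all
  exon_only <- toy_contig(8, 30L, 51L)
  expect_equal(count_ir(exon_only, intron, flanks)[["signal"]], 0)

  # a split read spanning the intron contributes to exon depth only
  spanning <- toy_split(4, 80L, 100L, 200L, 220L)
  got <- count_ir(spanning, intron, flanks, mode = "mean_depth")
  expect_equal(got[["signal"]], 0)
  expect_equal(got[["background"]], round(4 * 40 / 200))
  expect_equal(count_ir(spanning, intron, flanks, "read_count")[["signal"]], 0)

  expect_error(count_ir(aln, c(50, 50), flanks), class = "sr_validation_error")
})

test_that("exon-skipping counting uses strict gap containment", {
  exon <- c(300, 350)
  incl <- list(c(200, 300), c(350, 450))
  skips <- toy_split(7, 150L, 200L, 450L, 500L)       # gap contains the exon
  includes <- rbind(toy_split(9, 150L, 200L, 300L, 340L),
                    toy_split(4, 310L, 350L, 450L, 500L))
  partial <- toy_split(3, 150L, 200L, 320L, 360L)     # gap only half-covers
  aln <- rbind(skips, includes, partial)
  expect_equal(count_es(aln, exon, incl), c(signal = 7, background = 13))
  expect_equal(count_es(toy_contig(5, 0L, 21L), exon, incl),
               c(signal = 0, background = 0))
  expect_error(count_es(aln, exon, incl[1]), class = "sr_unsupported_event")
})

test_that("altDA counting distinguishes shared-site and all-split backgrounds", {
  au <- c(160, 1341); gu <- c(400, 1100)
  aln <- rbind(toy_split(10, 100L, au[1], au[2], 1400L),
               toy_split(4, 350L, gu[1], gu[2], 1150L))
  expect_equal(count_altda(aln, au), c(signal = 10, background = 0))
  expect_equal(count_altda(aln, au, background = "all_split"),
               c(signal = 10, background = 4))

  # two donor-acceptor pairs sharing a donor
  shared <- rbind(toy_split(6, 100L, 200L, 400L, 450L),
                  toy_split(9, 100L, 200L, 500L, 550L))
  expect_equal(count_altda(shared, c(200, 400)), c(signal = 6, background = 9))
  expect_equal(count_altda(toy_contig(5, 0L, 21L), au),
               c(signal = 0, background = 0))
})

test_that("replicate merging is element-wise accumulation", {
  expect_equal(merge_replicates(list(c(signal = 1, background = 2),
                                     c(signal = 3, background = 4),
                                     c(signal = 5, background = 6))),
               c(signal = 9, background = 12))
  expect_equal(merge_replicates(list(c(signal = 3, background = 1))),
               c(signal = 3, background = 1))
  expect_equal(merge_replicates(rep(list(c(signal = 0, background = 0)), 3)),
               c(signal = 0, background = 0))
  expect_error(merge_replicates(list()), class = "sr_validation_error")
})

test_that("the 2x2 statistic matches its closed form and handles degeneracy", {
  t0 <- chi2_test(c(signal = 50, background = 50),
                  c(signal = 50, background = 50))
  expect_equal(t0$chi2, 0)
  expect_equal(t0$p_value, 1)

  t1 <- chi2_test(c(signal = 30, background = 70),
                  c(signal = 60, background = 40))
  expect_equal(t1$chi2, 200 * (30 * 40 - 70 * 60)^2 / (100 * 100 * 90 * 110))
  expect_equal(t1$chi2, 18.1818, tolerance = 1e-4)
  expect_true(t1$significant)
  expect_equal(t1$direction, 1)

  tz <- chi2_test(c(signal = 0, background = 100),
                  c(signal = 0, background = 100))
  expect_equal(tz$p_value, 1)
  expect_false(tz$significant)

  expect_error(chi2_test(c(signal = -1, background = 5),
                         c(signal = 1, background = 5)),
               class = "sr_validation_error")
})

test_that("the statistic agrees with an independent oracle on random tables", {
  set.seed(20230804)
  for (i in 1:1000) {
    tab <- matrix(rpois(4, lambda = sample(c(5, 20, 100), 1)) + 1, 2)
    ours <- chi2_test(c(signal = tab[1, 1], background = tab[1, 2]),
                      c(signal = tab[2, 1], background = tab[2, 2]))
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("scaling both rows preserves direction and grows the statistic", {
  ctrl <- c(signal = 12, background = 40)
  trt <- c(signal = 25, background = 30)
  base <- chi2_test(ctrl, trt)
  for (k in c(2, 5, 10)) {
    scaled <- chi2_test(k * ctrl, k * trt)
    expect_equal(scaled$direction, base$direction)
    expect_gte(scaled$chi2, base$chi2)
  }
  # merging replicates then testing equals testing the summed counts
  reps_c <- list(c(signal = 3, background = 10), c(signal = 4, background = 15),
                 c(signal = 5, background = 15))
  reps_t <- list(c(signal = 9, background = 10), c(signal = 8, background = 10),
                 c(signal = 8, background = 10))
  expect_equal(chi2_test(merge_replicates(reps_c), merge_replicates(reps_t))$chi2,
               chi2_test(c(signal = 12, background = 40),
                         c(signal = 25, background = 30))$chi2)
})

test_that("a planted intron-retention difference is detected, identical groups are not", {
  cfg <- default_config(seed = 53)
  loc <- build_reporter_locus(cfg)
  grp <- function(unspliced, seeds, n = 800L) {
    lapply(seeds, function(s) {
      mix <- c(unspliced = unspliced, gu_ag = (1 - unspliced) * 0.6,
               au_ac = (1 - unspliced) * 0.4)
      c2 <- default_config(seed = s, variant_mix = mix,
                           n_rnaseq_read_pairs = n)
      a <- simulate_rnaseq(loc, c2, sequences = FALSE)
      a[a$mate == 1, ]
    })
  }
  res <- detect_events(grp(0.05, 1:3), grp(0.5, 4:6), loc)
  ir <- res[res$kind == "IR" & res$tested, ]
  expect_gt(nrow(ir), 0)
  expect_true(all(ir$p_value < 0.05))
  expect_true(all(ir$direction == 1))            # more retention in treatment

  # the exact null: both groups are the same simulated samples
  same <- grp(0.25, 11:13)
  res0 <- detect_events(same, same, loc)
  expect_equal(sum(res0$significant), 0)
  expect_true(all(res0$chi2[res0$tested] == 0))
})

test_that("sparse events are reported untested rather than tested on noise", {
  loc <- test_locus()
  a <- list(toy_split(2, 100L, 160L, 1341L, 1380L))
  res <- detect_events(a, a, loc, min_total = 10)
  expect_true(all(!res$tested[res$kind == "IR"] |
                  res$s_ctrl[res$kind == "IR"] +
                  res$b_ctrl[res$kind == "IR"] +
                  res$s_trt[res$kind == "IR"] +
                  res$b_trt[res$kind == "IR"] >= 10))
  expect_true(any(res$note == "below min_total"))
})
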