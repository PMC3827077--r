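small_cfg <- function(..., seed = 5L) {
  sim_config(chrom_lengths = c(chrA = 3e6, chrB = 3e6), seed = seed, ...)
}

test_that("het spacing matches the target distribution", {
  tpl <- make_template_normal(sim_config(
    chrom_lengths = c(chr1 = 8e6, chr2 = 8e6), seed = 2))
  het <- tpl$sites[tpl$sites$geno == "het", ]
  sp <- unlist(tapply(het$pos, het$chrom, diff))
  expect_gt(length(sp), 1e4)
  expect_gt(median(sp), 300)
  expect_lt(median(sp), 650)
})

test_that("template window medians track the base coverage", {
  tpl <- make_template_normal(small_cfg())
  expect_equal(median(tpl$windows$rd_med), 60, tolerance = 0.05)
  expect_equal(median(tpl$sites$rd_n), 60, tolerance = 0.1)
  # determinism under a fixed seed
  tpl2 <- make_template_normal(small_cfg())
  expect_identical(tpl$sites, tpl2$sites)
})

test_that("event regions carry the expected mixed somatic ratio", {
  ev <- data.frame(chrom = "chrA", start = 5e5, end = 2.5e6,
                   type = "double_deletion", subclonal_fraction = 1)
  cfg <- small_cfg(admixture_rate = 0.4)
  sim <- simulate_genome(cfg, ev)
  expect_equal(sim$truth$expected_ratio, 0.4)
  snps <- sim$snps
  inside <- snps$chrom == "chrA" & snps$pos > 5e5 & snps$pos <= 2.5e6
  # zero-truncation of the event-region draws adds ~0.4*sd reads, so the
  # realized double-deletion ratio sits slightly above the nominal 0.4
  expect_equal(mean(snps$rd_t[inside]) / mean(snps$rd_n[inside]), 0.4,
               tolerance = 0.1)
  outside <- snps$chrom == "chrB"
  expect_equal(mean(snps$rd_t[outside]) / mean(snps$rd_n[outside]), 1,
               tolerance = 0.03)
})

test_that("subclonal mixing composes with admixture in the forward model", {
  # 3 copies in 90% of cancer cells, no contamination -> ratio 1.45
  ev <- data.frame(chrom = "chrA", start = 5e5, end = 2.5e6,
                   type = "gain1", subclonal_fraction = 0.9)
  sim <- simulate_genome(small_cfg(admixture_rate = 0), ev)
  expect_equal(sim$truth$expected_ratio, 1.45)
  snps <- sim$snps
  inside <- snps$chrom == "chrA" & snps$pos > 5e5 & snps$pos <= 2.5e6
  expect_equal(mean(snps$rd_t[inside]) / mean(snps$rd_n[inside]), 1.45,
               tolerance = 0.03)
})

test_that("LOH regions show the admixture-implied LAF, not zero", {
  ev <- data.frame(chrom = "chrA", start = 5e5, end = 2.5e6,
                   type = "LOH", subclonal_fraction = 1)
  sim <- simulate_genome(small_cfg(admixture_rate = 0.4), ev)
  snps <- sim$snps
  het_in <- snps$geno == "het" & snps$chrom == "chrA" &
    snps$pos > 5e5 & snps$pos <= 2.5e6
  # B_mix/C_mix = 0.4 / 1.4 (mirroring pulls the median slightly low)
  expect_lt(abs(median(snps$laf_t[het_in]) - 0.4 / 1.4), 0.02)
})

test_that("binomial thinning preserves ratios and means", {
  expect_identical(downsample(c(5, 9, 20), 60, 60), c(5, 9, 20))
  set.seed(6)
  x <- rpois(20000, 60)
  th <- downsample(x, 60, 20, seed = 3)
  expect_equal(mean(th) / mean(x), 1 / 3, tolerance = 0.02)
  # thinning both libraries preserves the somatic ratio of an event
  ev <- data.frame(chrom = "chrA", start = 5e5, end = 2.5e6,
                   type = "gain2", subclonal_fraction = 1)
  s60 <- simulate_genome(small_cfg(admixture_rate = 0.2), ev)
  s20 <- simulate_genome(small_cfg(admixture_rate = 0.2,
                                   downsample_to = 20), ev)
  inside <- s60$snps$chrom == "chrA" & s60$snps$pos > 5e5 &
    s60$snps$pos <= 2.5e6
  r60 <- mean(s60$snps$rd_t[inside]) / mean(s60$snps$rd_n[inside])
  r20 <- mean(s20$snps$rd_t[inside]) / mean(s20$snps$rd_n[inside])
  expect_equal(r60, r20, tolerance = 0.05)
  expect_equal(mean(s20$snps$rd_n) / mean(s60$snps$rd_n), 1 / 3,
               tolerance = 0.05)
})

test_that("overlapping events are rejected", {
  ev <- data.frame(chrom = "chrA", start = c(5e5, 1e6), end = c(2e6, 3e6),
                   type = "LOH", subclonal_fraction = 1)
  tpl <- make_template_normal(small_cfg())
  expect_error(place_events_and_mix(tpl, ev, small_cfg()), "overlap")
})

test_that("score_calls implements the positive-call and matching rules", {
  truth <- data.frame(chrom = "chr1", start = c(1e6, 8e6), end = c(3e6, 8.5e6),
                      type = "LOH", subclonal_fraction = c(1, 0.4))
  # perfect calls: sensitivity 1, precision 1, one segment per event
  calls <- data.frame(chrom = "chr1",
                      start = c(0, 1e6, 3e6, 8e6, 8.5e6),
                      end = c(1e6, 3e6, 8e6, 8.5e6, 1e7),
                      somatic_ratio = c(1, 0.6, 1, 0.7, 1),
                      classification = c("neutral", "clonal", "neutral",
                                         "subclonal", "neutral"))
  sc <- score_calls(calls, truth)
  expect_equal(sc$sensitivity, 1)
  expect_equal(sc$precision, 1)
  expect_equal(sc$segments_per_large_event, 1)
  expect_equal(sc$subclonal_recovered, 1)
  expect_equal(sc$subclonal_fp, 0)
  # ratio 0.75 is a positive call; 1.0 is not; breakpoints beyond 100 kb fail
  calls2 <- data.frame(chrom = "chr1", start = c(1.2e6), end = c(3.05e6),
                       somatic_ratio = 0.75)
  sc2 <- score_calls(calls2, truth)
  expect_equal(sc2$n_pos, 1L)
  expect_equal(sc2$n_tp, 0L)          # start off by 200 kb
  calls3 <- data.frame(chrom = "chr1", start = 1.05e6, end = 2.95e6,
                       somatic_ratio = 1.0)
  expect_equal(score_calls(calls3, truth)$n_pos, 0L)
})

test_that("event layouts satisfy the stated invariants", {
  for (k in c("subclonal", "small")) {
    for (r in 1:3) {
      lay <- sim_event_layout(k, replicate = r)
      ev <- lay$events
      expect_true(all(ev$end - ev$start >= 1e4))        # >= 10 kb
      expect_true(all(ev$end <= lay$chrom_lengths[ev$chrom]))
      for (ch in unique(ev$chrom)) {                     # non-overlapping
        e <- ev[ev$chrom == ch, ]
        e <- e[order(e$start), ]
        if (nrow(e) > 1) expect_true(all(e$start[-1] >= e$end[-nrow(e)]))
      }
    }
  }
  # subclonal layout: 4-5 events > 10 Mb at fractions 0.2/0.4 on chr12-15
  lay <- sim_event_layout("subclonal", replicate = 1)
  sub <- lay$events[lay$events$subclonal_fraction < 1, ]
  expect_true(nrow(sub) %in% 4:5)
  expect_true(all(sub$end - sub$start > 1e7))
  expect_true(all(sub$subclonal_fraction %in% c(0.2, 0.4)))
  expect_true(all(sub$chrom %in% paste0("chr", 12:15)))
})
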