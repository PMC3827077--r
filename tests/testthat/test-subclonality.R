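test_that("normal allelic copies split total copy by germline balance", {
  expect_equal(normal_allelic_copy(1, 0.5), c(nA = 1L, nB = 1L))
  expect_equal(normal_allelic_copy(1, 0.0), c(nA = 2L, nB = 0L))
  expect_equal(normal_allelic_copy(1.5, 1 / 3), c(nA = 2L, nB = 1L))
})

test_that("one-copy clonal test follows the stated decision rule", {
  # observed ratio exactly at the clonal gain value: clonal
  t1 <- test_one_copy_clonal(1.5, 1, 1, sigma = 1e-3)
  expect_equal(t1$direction, "gain")
  expect_equal(t1$r_clonal, 1.5)
  expect_gt(t1$p_value, 0.99)
  expect_equal(t1$classification, "clonal")
  # five null SDs away: subclonal
  t2 <- test_one_copy_clonal(1.45, 1, 1, sigma = 0.01)
  expect_lt(t2$p_value, 0.05)
  expect_equal(t2$classification, "subclonal")
  # adjusted ratio of exactly 1 is copy-neutral, not tested
  t3 <- test_one_copy_clonal(1, 1, 1, sigma = 0.01)
  expect_equal(t3$classification, "neutral")
  expect_true(is.na(t3$p_value))
  # loss below zero copies is impossible
  expect_error(test_one_copy_clonal(0.6, 1, 0, sigma = 0.01), "below zero")
  # classification flips exactly at the threshold
  sigma <- 0.02
  delta <- sigma * qnorm(1 - 0.025)   # p = 0.05 at this deviation
  p_at <- test_one_copy_clonal(1.5 - delta, 1, 1, sigma)$p_value
  expect_equal(p_at, 0.05, tolerance = 1e-10)
  expect_equal(test_one_copy_clonal(1.5 - delta * 0.99, 1, 1,
                                    sigma)$classification, "clonal")
  expect_equal(test_one_copy_clonal(1.5 - delta * 1.01, 1, 1,
                                    sigma)$classification, "subclonal")
})

test_that("subclonal fraction reproduces the worked gain example", {
  out <- subclonal_fraction(1.45, 1, 1, "gain", laf_t = 0.45, laf_g = 0.5)
  expect_equal(out$f, 0.9)
  expect_equal(out$nA_t + out$nB_t, 3L)
  # fully clonal limit and no-aberration limit
  expect_equal(subclonal_fraction(1.5, 1, 1, "gain", 0.4, 0.5)$f, 1)
  expect_equal(subclonal_fraction(1.0, 1, 1, "gain", 0.5, 0.5)$f, 0)
  # allele choice: LAF toward 0.5 means the lesser allele gained
  gain_toward <- subclonal_fraction(1.3, 1, 1, "gain", 0.5, 0.45)
  expect_equal(c(gain_toward$nA_t, gain_toward$nB_t), c(1L, 2L))
  loss_away <- subclonal_fraction(0.7, 1, 1, "loss", 0.2, 0.45)
  expect_equal(c(loss_away$nA_t, loss_away$nB_t), c(1L, 0L))
})

test_that("multi-copy subclones share one expected ratio (identifiability)", {
  expect_equal(expected_subclonal_ratio(5, 0.30), 1.45)
  expect_equal(expected_subclonal_ratio(4, 0.45), 1.45)
  expect_equal(expected_subclonal_ratio(3, 0.90), 1.45)
  expect_equal(expected_subclonal_ratio(2, runif(1)), 1)
})

test_that("subclonal_fraction inverts the forward model for 1-copy events", {
  for (f in seq(0.05, 0.95, by = 0.05)) {
    r <- expected_subclonal_ratio(3, f)     # one-copy gain from (1,1)
    expect_equal(subclonal_fraction(r, 1, 1, "gain", 0.45, 0.5)$f, f,
                 tolerance = 1e-12)
    r2 <- expected_subclonal_ratio(1, f)    # one-copy loss from (1,1)
    expect_equal(subclonal_fraction(r2, 1, 1, "loss", 0.3, 0.5)$f, f,
                 tolerance = 1e-12)
  }
})

test_that("bootstrap SD shrinks with segment size", {
  set.seed(31)
  rd_n1 <- rpois(100, 60); rd_t1 <- rpois(100, 60)
  rd_n2 <- rpois(1600, 60); rd_t2 <- rpois(1600, 60)
  s1 <- bootstrap_ratio_sd(rd_t1, rd_n1, n_boot = 100, seed = 1)
  s2 <- bootstrap_ratio_sd(rd_t2, rd_n2, n_boot = 100, seed = 1)
  expect_gt(s1, 0)
  expect_lt(s2, s1)          # ~4x more SNPs -> ~2x smaller SD
})

test_that("characterize_subclonality classifies a constructed genome", {
  # segments: neutral, clonal one-copy gain, subclonal gain (f = 0.4),
  # clonal double deletion -- at alpha = 0.4
  alpha <- 0.4
  r_obs <- alpha + (1 - alpha) * c(1, 1.5, 1.2, 0) # observed somatic ratios
  set.seed(8)
  n_per <- 400L
  snps <- data.table::data.table(
    chrom = "chr1", pos = seq_len(4 * n_per) * 500, geno = "het",
    rd_n = rpois(4 * n_per, 80),
    laf_n = 0.48, ratio_n = 1)
  snps$rd_t_use <- rpois(4 * n_per, 80 * rep(r_obs, each = n_per))
  snps$rd_t <- snps$rd_t_use
  snps$laf_t <- rep(c(0.48, 0.33, 0.42, 0.49), each = n_per)
  segs <- toy_segments(r_obs, n_per = n_per)
  segs$somatic_ratio <- vapply(seq_len(4), function(k)
    estimate_somatic_ratio(snps$rd_t_use[segs$snp_first[k]:segs$snp_last[k]],
                           snps$rd_n[segs$snp_first[k]:segs$snp_last[k]]),
    numeric(1))
  out <- characterize_subclonality(segs, snps, alpha, scna_config(seed = 4))
  expect_equal(out$classification,
               c("neutral", "clonal", "subclonal", "clonal"))
  expect_equal(out$event[2], "gain")
  expect_equal(out$f[3], 0.4, tolerance = 0.1)
  expect_equal(out$event[4], "loss")       # double deletion: total copy 0
  expect_equal(out$nA_t[4] + out$nB_t[4], 0L)
})
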