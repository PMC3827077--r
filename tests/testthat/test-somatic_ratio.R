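test_that("identical libraries give ratio 1 for every estimator", {
  set.seed(1)
  rd <- rpois(100, 60) + 1
  for (m in c("gh_mle", "geometric_mean", "mean_ratio")) {
    expect_equal(estimate_somatic_ratio(rd, rd, method = m), 1,
                 tolerance = 1e-4)
  }
})

test_that("exact doubling is recovered by the GH MLE", {
  rd_n <- rep(60, 50)
  r <- estimate_somatic_ratio(2 * rd_n, rd_n)
  expect_equal(r, 2, tolerance = 2e-3)
})

test_that("GH MLE is consistent on Poisson pairs (r = 1.3)", {
  est <- vapply(1:100, function(s) {
    set.seed(s)
    rd_n <- rpois(200, 60)
    rd_t <- rpois(200, 78)
    estimate_somatic_ratio(rd_t, rd_n)
  }, numeric(1))
  expect_lt(abs(median(est) - 1.3), 0.02)
})

test_that("GH MLE and geometric mean agree on balanced Poisson data", {
  set.seed(5)
  for (lam in c(30, 60)) {
    rd_n <- rpois(300, lam) + 1
    rd_t <- rpois(300, lam) + 1
    a <- estimate_somatic_ratio(rd_t, rd_n, method = "gh_mle")
    b <- estimate_somatic_ratio(rd_t, rd_n, method = "geometric_mean")
    expect_lt(abs(a - b), 0.03)
  }
})

test_that("percentile trimming drops extreme pairs and zeros are handled", {
  rd_n <- c(rep(60, 98), 60, 0)
  rd_t <- c(rep(60, 98), 6000, 10)   # one absurd ratio, one zero-normal
  expect_message(r <- estimate_somatic_ratio(rd_t, rd_n), "zero normal")
  expect_equal(r, 1, tolerance = 0.01)
  expect_error(estimate_somatic_ratio(numeric(0), numeric(0)))
})

test_that("merge_refine follows the paper's merge rule", {
  # adjacent ratios 1.00 / 1.04 merge (diff < 0.05); 1.0 / 1.2 do not
  snps <- toy_segment_snps(c(1.00, 1.04, 1.20))
  segs <- toy_segments(c(1.00, 1.04, 1.20))
  out <- merge_refine(segs, snps, T = 0.05)
  expect_equal(nrow(out), 2L)
  expect_equal(out$somatic_ratio[1], 1.02, tolerance = 0.01)
  expect_equal(out$end[1], segs$end[2])

  # three segments 1.00, 1.03, 1.30: boundary survives at the 1.03/1.30 gap
  snps2 <- toy_segment_snps(c(1.00, 1.03, 1.30))
  segs2 <- toy_segments(c(1.00, 1.03, 1.30))
  out2 <- merge_refine(segs2, snps2, T = 0.05)
  expect_equal(nrow(out2), 2L)
  expect_equal(out2$end[1], segs2$end[2])
})

test_that("merge_refine is a fixed point and preserves interval cover", {
  set.seed(9)
  ratios <- c(1.0, 1.02, 1.01, 1.4, 1.42, 0.7)
  snps <- toy_segment_snps(ratios)
  segs <- toy_segments(ratios)
  once <- merge_refine(segs, snps, T = 0.05)
  twice <- merge_refine(once, snps, T = 0.05)
  expect_identical(once, twice)
  expect_equal(min(once$start), min(segs$start))
  expect_equal(max(once$end), max(segs$end))
  expect_equal(once$start[-1], once$end[-nrow(once)])
  # no adjacent pair differs by less than T
  expect_true(all(abs(diff(once$somatic_ratio)) >= 0.05))
})

test_that("segments under 5 het markers are absorbed", {
  snps <- toy_segment_snps(c(1.0, 1.5, 1.0), n_per = 60L)
  segs <- toy_segments(c(1.0, 1.5, 1.0), n_per = 60L)
  segs$n_het[2] <- 3L      # below resolution: absorbed into a neighbor
  out <- merge_refine(segs, snps, T = 0.05, min_het_seg = 5L)
  expect_true(all(out$n_het >= 5L))
  expect_lt(nrow(out), 3L)
  expect_equal(min(out$start), min(segs$start))
  expect_equal(max(out$end), max(segs$end))
})
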