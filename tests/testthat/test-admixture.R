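test_that("expected somatic ratio reproduces the admixture arithmetic", {
  expect_equal(expected_somatic_ratio(c(0, 1, 3, 4), 0.4),
               c(0.4, 0.7, 1.3, 1.6))
  expect_equal(expected_somatic_ratio(1, 0.6), 0.8)
  expect_equal(expected_somatic_ratio(3, 0.6), 1.2)
  # copy 2 is the anchor at every admixture rate; the model is affine in c
  for (a in seq(0, 0.9, by = 0.1)) {
    expect_equal(expected_somatic_ratio(2, a), 1)
    d <- diff(expected_somatic_ratio(0:4, a))
    expect_equal(d, rep(d[1], 4))
  }
  # adjustment inverts the forward model
  expect_equal(adjust_somatic_ratio(expected_somatic_ratio(3, 0.4), 0.4), 1.5)
})

test_that("alpha is recovered exactly from noiseless clonal levels", {
  for (a in c(0, 0.2, 0.4, 0.6)) {
    lv <- 2 * expected_somatic_ratio(0:4, a)
    expect_equal(estimate_alpha(lv, 0:4), a, tolerance = 1e-12)
  }
  expect_warning(a0 <- estimate_alpha(c(2, 2), c(2L, 2L)), "undefined")
  expect_equal(a0, 0)
  # cap at 0.8
  lv <- 2 * expected_somatic_ratio(c(0, 1, 3), 0.95)
  expect_equal(estimate_alpha(lv, c(0, 1, 3)), 0.8)
})

test_that("alpha is recovered within 0.05 from noisy levels", {
  set.seed(11)
  copies <- rep(c(0, 1, 2, 3, 4), 4)
  lv <- 2 * expected_somatic_ratio(copies, 0.6) + rnorm(20, 0, 0.05)
  expect_lt(abs(estimate_alpha(lv, copies) - 0.6), 0.05)
})

test_that("component count is selected by AIC with a 0.2 center gap", {
  set.seed(12)
  lv <- rep(c(1.4, 2.0, 2.6), each = 10) + rnorm(30, 0, 0.05)
  sel <- select_component_count(lv)
  expect_equal(sel$K, 3L)
  expect_lt(max(abs(sort(sel$centers) - c(1.4, 2.0, 2.6))), 0.1)
  expect_true(all(diff(sel$centers) >= 0.2))

  # two tight clusters 0.1 apart may not produce centers closer than 0.2
  lv2 <- c(rnorm(15, 2.0, 0.02), rnorm(15, 2.1, 0.02), rnorm(10, 3, 0.02))
  sel2 <- select_component_count(lv2)
  expect_true(all(diff(sel2$centers) >= 0.2))

  # degenerate single level floors at K = 3
  sel3 <- select_component_count(rep(2, 10))
  expect_equal(sel3$K, 3L)
})

test_that("component order maps to integer copies anchored at level 2", {
  expect_equal(as.integer(map_copy_states(c(0.8, 1.4, 2.0, 2.6, 3.2))), 0:4)
  expect_equal(as.integer(map_copy_states(c(0.4, 1.2, 2.0, 2.8, 3.6))), 0:4)
  # a missing intermediate level does not shift the outer copies
  expect_equal(as.integer(map_copy_states(c(0.8, 2.0, 2.6, 3.2))),
               c(0L, 2L, 3L, 4L))
  expect_equal(as.integer(map_copy_states(2)), 2L)
})

test_that("MCMC allocation separates clear and ambiguous levels", {
  lv <- c(rep(1, 5), rep(2, 5), 1.85, 1.5)
  fit <- mh_assign(lv, centers = c(1, 2, 3), seed = 3)
  # level 1.85 confidently assigned integer copy 2
  expect_equal(fit$copy[11], 2L)
  expect_gt(fit$posterior[11], 0.95)
  # level 1.5 sits between copy 1 and copy 2: ambiguous
  expect_lt(fit$posterior[12], 0.9)
  expect_true(all(fit$posterior >= 0 & fit$posterior <= 1))
  # monotone: a higher level never gets a lower copy state
  ord <- order(lv)
  expect_true(all(diff(fit$copy[ord]) >= 0))
})

test_that("the chain is bit-reproducible under a fixed seed", {
  lv <- c(rep(0.8, 3), rep(2, 6), rep(2.6, 3)) + seq(-0.01, 0.01, length = 12)
  f1 <- mh_assign(lv, centers = c(0.8, 2, 2.6), seed = 77)
  f2 <- mh_assign(lv, centers = c(0.8, 2, 2.6), seed = 77)
  expect_identical(f1, f2)
})

test_that("fit_admixture estimates alpha from clonal segments only", {
  set.seed(14)
  copies <- c(0, 1, 2, 2, 2, 3, 4, 2, 2, 1, 3, 2)
  lv <- 2 * expected_somatic_ratio(copies, 0.4) + rnorm(12, 0, 0.02)
  lv <- c(lv, 2.3)   # one ambiguous level between copies 2 and 3 at a=0.4
  segs <- data.frame(somatic_ratio = lv / 2,
                     n_snps = rep(500L, length(lv)))
  fit <- fit_admixture(segs, scna_config(seed = 5))
  expect_lt(abs(fit$alpha - 0.4), 0.05)
  expect_true(all(fit$clonality %in% c("clonal", "candidate_subclonal")))
})
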