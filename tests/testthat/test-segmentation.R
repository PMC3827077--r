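test_that("a clear step is found within 5 points of the true boundary", {
  set.seed(10)
  x <- c(rnorm(200, 0.48, 0.03), rnorm(200, 0.25, 0.03))
  cps <- cbs_overdetect(x, seed = 3)
  pruned <- lars_bic_prune(x, cps)
  expect_length(pruned, 1L)
  expect_lte(abs(pruned - 200L), 5L)
  # agrees with the exhaustive single-split t-scan oracle
  expect_lte(abs(pruned - oracle_best_split(x)), 5L)
})

test_that("noise-only sequences end with a single segment", {
  hits <- vapply(1:10, function(s) {
    set.seed(100 + s)
    x <- rnorm(500, 0.4, 0.05)
    length(lars_bic_prune(x, cbs_overdetect(x, seed = s)))
  }, numeric(1))
  # false-positive control: >= 90% of seeds give one segment
  expect_gte(mean(hits == 0), 0.9)
})

test_that("degenerate inputs give no change points", {
  expect_identical(cbs_overdetect(rep(0.4, 50)), integer(0))
  expect_identical(cbs_overdetect(rnorm(5)), integer(0))
  expect_identical(lars_bic_prune(rnorm(50), integer(0)), integer(0))
})

test_that("pruning is a subset of the candidates and matches the
           exhaustive BIC oracle on planted cases", {
  set.seed(20)
  for (rep_i in 1:5) {
    x <- c(rnorm(120, 0.45, 0.04), rnorm(120, 0.30, 0.04))
    cps <- c(60L, 120L, 180L, 200L)   # one true (120), three spurious
    pruned <- lars_bic_prune(x, cps)
    expect_true(all(pruned %in% cps))
    expect_identical(pruned, oracle_bic_subset(x, cps))
    expect_identical(pruned, 120L)
  }
})

test_that("two candidates straddling one step collapse to one", {
  set.seed(30)
  x <- c(rnorm(150, 0.45, 0.03), rnorm(150, 0.28, 0.03))
  pruned <- lars_bic_prune(x, c(149L, 151L))
  expect_length(pruned, 1L)
  expect_true(pruned %in% c(149L, 151L))
})

test_that("padding seed does not move well-separated change points", {
  set.seed(40)
  x <- c(rnorm(300, 0.46, 0.03), rnorm(300, 0.20, 0.03))
  cp1 <- lars_bic_prune(x, cbs_overdetect(x, seed = 1))
  cp2 <- lars_bic_prune(x, cbs_overdetect(x, seed = 99))
  expect_equal(cp1, cp2, tolerance = 0)
})

test_that("segment_chromosome emits a consistent per-chromosome table", {
  set.seed(50)
  pos <- sort(sample.int(2e6, 800))
  laf <- c(rnorm(400, 0.46, 0.04), rnorm(400, 0.25, 0.04))
  seg <- segment_chromosome(pos, pmin(pmax(laf, 0), 0.5))
  expect_equal(seg$first_idx[1], 1L)
  expect_equal(seg$last_idx[nrow(seg)], 800L)
  expect_true(all(diff(seg$start) > 0))
  expect_equal(seg$start[-1], seg$end[-nrow(seg)])  # half-open adjacency
  expect_equal(sum(seg$n_het), 800L)
})
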