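test_that("constant and near-threshold sequences pass through unchanged", {
  x <- rep(0.45, 20)
  expect_identical(smooth_laf(x), x)              # zero SD regions
  set.seed(1)
  y <- runif(50, 0.3, 0.5)
  expect_identical(smooth_laf(y, t = 1e6), y)     # huge threshold: identity
})

test_that("an isolated spike is replaced by the region median", {
  # hand oracle: region {0.5 x6, 0}: mean 3/7, sd sqrt(0.2143/6) = 0.1890,
  # |0 - 0.4286| = 0.4286 > 2 * 0.1890 -> replaced by median 0.5
  x <- c(rep(0.5, 6), 0, rep(0.5, 6))
  out <- smooth_laf(x, half_width = 3, t = 2)
  expect_equal(out[7], 0.5)
  expect_identical(out[-7], x[-7])                # all others bitwise same
})

test_that("a spike inside a 5-point region at t = 2 is NOT replaced", {
  # hand oracle: region {0.5,0.5,0,0.5,0.5}: mean 0.4, sample sd 0.2236,
  # |0 - 0.4| = 0.4 < 2 * 0.2236 = 0.4472 -> the point stays
  x <- c(rep(0.5, 3), 0, rep(0.5, 3))
  out <- smooth_laf(x, half_width = 2, t = 2)
  expect_identical(out, x)
})

test_that("short input warns and is returned unchanged", {
  x <- c(0.1, 0.5, 0.3)
  expect_warning(out <- smooth_laf(x, half_width = 5), "shorter")
  expect_identical(out, x)
})

test_that("smoothing never invents values and uses original statistics", {
  set.seed(42)
  for (rep_i in 1:5) {
    x <- pmin(pmax(rnorm(200, 0.4, 0.08), 0), 0.5)
    x[sample(200, 5)] <- 0                        # plant spikes
    out <- smooth_laf(x, half_width = 5, t = 2)
    expect_length(out, length(x))
    # every output value is the original or some window median of originals
    meds <- vapply(seq_along(x), function(i) {
      median(x[max(1, i - 5):min(200, i + 5)])
    }, numeric(1))
    ok <- out == x | abs(out - meds) < 1e-12
    expect_true(all(ok))
    expect_true(all(out >= min(x) & out <= max(x)))
  }
})
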