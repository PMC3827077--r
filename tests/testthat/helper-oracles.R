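# Independent oracles used by the unit and acceptance tests.

# RSS of the piecewise-constant fit of x with change points cps
oracle_pc_rss <- function(x, cps) {
  b <- c(0L, sort(cps), length(x))
  sum(vapply(seq_len(length(b) - 1L), function(k) {
    seg <- x[(b[k] + 1L):b[k + 1L]]
    sum((seg - mean(seg))^2)
  }, numeric(1)))
}

# exhaustive-subset BIC oracle (same criterion as the implementation);
# ties broken toward fewer change points
oracle_bic_subset <- function(x, cps, variant = "cumseg") {
  n <- length(x)
  Cn <- if (variant == "cumseg") log(log(max(n, 8))) else 1
  best <- integer(0)
  best_bic <- n * log(max(oracle_pc_rss(x, integer(0)), 1e-12) / n)
  K <- length(cps)
  if (K == 0L) return(best)
  for (m in seq_len(2^K - 1L)) {
    sub <- cps[bitwAnd(m, 2^(seq_len(K) - 1L)) > 0]
    bic <- n * log(max(oracle_pc_rss(x, sub), 1e-12) / n) +
      length(sub) * log(n) * Cn
    if (bic < best_bic - 1e-9 ||
        (abs(bic - best_bic) <= 1e-9 && length(sub) < length(best))) {
      best_bic <- bic
      best <- sort(sub)
    }
  }
  best
}

# dense-grid Geary-Hinkley likelihood oracle (pure R)
oracle_gh_grid <- function(rd_t, rd_n, step = 0.001, lo = 0.01, hi = 8) {
  rgrid <- seq(lo, hi, by = step)
  ll <- vapply(rgrid, function(r) {
    z <- (r * rd_n - rd_t) / sqrt(r^2 * rd_n + rd_t)
    -0.5 * sum(z^2)
  }, numeric(1))
  rgrid[which.max(ll)]
}

# exhaustive single-split t-scan (oracle for the dominant split location)
oracle_best_split <- function(x) {
  n <- length(x)
  s <- sd(x)
  ts <- vapply(seq_len(n - 1L), function(c) {
    m1 <- mean(x[1:c]); m2 <- mean(x[(c + 1L):n])
    abs(m1 - m2) / (s * sqrt(1 / c + 1 / (n - c)))
  }, numeric(1))
  which.max(ts)
}

# build a minimal SNP table for ratio/subclonality tests: depths chosen so
# the per-segment ratio estimate lands on the requested value
toy_segment_snps <- function(ratios, n_per = 60L, depth = 60) {
  ns <- length(ratios)
  data.table::data.table(
    chrom = "chr1",
    pos = seq_len(ns * n_per) * 1000,
    geno = "het",
    rd_t = rep(ratios, each = n_per) * depth,
    rd_n = depth,
    laf_t = 0.48, laf_n = 0.48,
    ratio_n = 1, rd_t_use = rep(ratios, each = n_per) * depth)
}

toy_segments <- function(ratios, n_per = 60L) {
  ns <- length(ratios)
  data.frame(
    chrom = "chr1",
    start = (seq_len(ns) - 1L) * n_per * 1000,
    end = seq_len(ns) * n_per * 1000,
    snp_first = (seq_len(ns) - 1L) * n_per + 1L,
    snp_last = seq_len(ns) * n_per,
    n_het = n_per, n_snps = n_per,
    somatic_ratio = ratios)
}
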