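#' @name somatic_ratio
#' @title Per-segment somatic ratio estimation and segment refinement
#' @description The somatic ratio of a segment is the tumor-to-normal
#'   read-depth ratio; 1 is copy-neutral when the two libraries have equal
#'   coverage.  The default estimator models the paired depths as normal
#'   approximations to Poisson counts and maximizes the summed log density
#'   of the Geary-Hinkley transform, which is standard normal at the true
#'   ratio.
NULL

.golden_max <- function(f, lo, hi, tol = 1e-6) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    }
  }
  (a + b) / 2
}

#' Estimate the somatic ratio of one segment
#'
#' @param rd_t,rd_n paired tumor/normal read depths of the segment's SNPs
#'   (heterozygous and homozygous sites both contribute).
#' @param method `"gh_mle"` (Geary-Hinkley transformed MLE, default),
#'   `"geometric_mean"` (of per-SNP depth ratios) or `"mean_ratio"`
#'   (ratio of the two Poisson-mean MLEs).
#' @param trim percentile pair; SNP pairs whose per-SNP ratio falls below
#'   the first or above the second percentile within the segment are
#'   excluded before estimation (default `c(5, 95)`).
#' @param grid search range for the MLE (default `c(0.01, 8)`).
#' @param grid_step coarse grid step before golden-section refinement.
#' @return The estimated ratio (a single non-negative number).
#' @examples
#' estimate_somatic_ratio(rep(60, 50), rep(60, 50))
#' @export
estimate_somatic_ratio <- function(rd_t, rd_n,
                                   method = c("gh_mle", "geometric_mean",
                                              "mean_ratio"),
                                   trim = c(5, 95), grid = c(0.01, 8),
                                   grid_step = 0.01) {
  method <- match.arg(method)
  stopifnot(length(rd_t) == length(rd_n))
  keep <- rd_n > 0
  n_zero <- sum(!keep)
  if (n_zero) message(n_zero, " pair(s) with zero normal depth dropped")
  rd_t <- rd_t[keep]; rd_n <- rd_n[keep]
  if (!length(rd_t)) stop("no usable SNP pairs in segment")
  q <- rd_t / rd_n
  qs <- quantile(q, trim / 100, names = FALSE)
  inside <- q >= qs[1] & q <= qs[2]
  if (any(inside)) { rd_t <- rd_t[inside]; rd_n <- rd_n[inside]; q <- q[inside] }
  if (!length(rd_t)) stop("no SNP pairs left after percentile trimming")
  switch(method,
    gh_mle = {
      rgrid <- seq(grid[1], grid[2], by = grid_step)
      ll <- cpp_gh_loglik(rd_t, rd_n, rgrid)
      i <- which.max(ll)
      lo <- rgrid[max(1L, i - 1L)]; hi <- rgrid[min(length(rgrid), i + 1L)]
      .golden_max(function(r) cpp_gh_loglik(rd_t, rd_n, r), lo, hi)
    },
    geometric_mean = {
      pos <- q > 0
      if (!any(pos)) stop("no positive depth ratios for geometric mean")
      exp(mean(log(q[pos])))
    },
    mean_ratio = mean(rd_t) / mean(rd_n))
}

#' Merge adjacent segments with near-equal somatic ratios
#'
#' Repeatedly merges the adjacent same-chromosome pair with the smallest
#' somatic-ratio difference while that difference is below `T`; the merged
#' segment's ratio is re-estimated from its pooled SNP pairs.  Iterated to a
#' fixed point, so running the function twice equals running it once, and
#' the union of output intervals equals the union of input intervals.
#'
#' @param segments data.frame with columns `chrom`, `start`, `end`,
#'   `snp_first`, `snp_last` (row range into `snps`) and `somatic_ratio`.
#' @param snps SNP table sorted identically to the one used to build the
#'   index ranges, with depth columns `rd_t_use` (or `rd_t`) and `rd_n`.
#' @param T merge tolerance on the ratio difference (default 0.05).
#' @param cfg configuration (ratio section controls the estimator).
#' @param min_het_seg segments with fewer heterozygous markers than this
#'   are absorbed into the adjacent segment with the closer ratio before
#'   merging (aberrations below 5 het sites are outside the method's
#'   resolution); set to 0 to disable.
#' @return The merged segment data.frame, ratios re-estimated.
#' @export
merge_refine <- function(segments, snps, T = 0.05, cfg = scna_config(),
                         min_het_seg = 5L) {
  segments <- as.data.frame(segments)
  if (nrow(segments) < 2L) return(segments)
  rd_t <- if (!is.null(snps$rd_t_use)) snps$rd_t_use else snps$rd_t
  rd_n <- snps$rd_n
  est <- function(a, b) estimate_somatic_ratio(
    rd_t[a:b], rd_n[a:b], method = cfg$ratio$method, trim = cfg$ratio$trim,
    grid = cfg$ratio$grid, grid_step = cfg$ratio$grid_step)
  merge_into <- function(segments, k, tgt) {
    # fold segment k into adjacent segment tgt (tgt = k - 1 or k + 1)
    lo <- min(k, tgt); hi <- max(k, tgt)
    segments$end[lo] <- segments$end[hi]
    segments$snp_last[lo] <- segments$snp_last[hi]
    if (!is.null(segments$last_idx)) {
      segments$last_idx[lo] <- segments$last_idx[hi]
      segments$n_het[lo] <- segments$n_het[lo] + segments$n_het[hi]
    }
    if (!is.null(segments$n_snps))
      segments$n_snps[lo] <- segments$n_snps[lo] + segments$n_snps[hi]
    segments$somatic_ratio[lo] <- est(segments$snp_first[lo],
                                      segments$snp_last[lo])
    segments[-hi, , drop = FALSE]
  }
  if (min_het_seg > 0L && !is.null(segments$n_het)) {
    repeat {
      small <- which(segments$n_het < min_het_seg)
      if (!length(small) || nrow(segments) < 2L) break
      done <- FALSE
      for (k in small) {
        nb <- c(k - 1L, k + 1L)
        nb <- nb[nb >= 1L & nb <= nrow(segments)]
        nb <- nb[segments$chrom[nb] == segments$chrom[k]]
        if (!length(nb)) next
        tgt <- nb[which.min(abs(segments$somatic_ratio[nb] -
                                  segments$somatic_ratio[k]))]
        segments <- merge_into(segments, k, tgt)
        done <- TRUE
        break
      }
      if (!done) break
    }
  }
  ratio_merge <- function(segments) {
    repeat {
      if (nrow(segments) < 2L) break
      i <- seq_len(nrow(segments) - 1L)
      same <- segments$chrom[i] == segments$chrom[i + 1L]
      d <- abs(segments$somatic_ratio[i] - segments$somatic_ratio[i + 1L])
      d[!same] <- Inf
      k <- which.min(d)                    # smallest difference first
      if (!is.finite(d[k]) || d[k] >= T) break
      segments <- merge_into(segments, k + 1L, k)
    }
    segments
  }
  # undo "blips": a short interior segment whose flanks belong to the same
  # aberration (flank ratios within T of each other) and whose own ratio
  # deviates from them by less than 3T is a residual over-detection from
  # window-level count noise; a true one-copy step at any admixture rate
  # where small events are testable shifts the ratio by at least 4T
  find_blip <- function(segments) {
    if (nrow(segments) < 3L || is.null(segments$n_het)) return(0L)
    for (k in 2:(nrow(segments) - 1L)) {
      if (segments$chrom[k - 1L] != segments$chrom[k] ||
          segments$chrom[k + 1L] != segments$chrom[k]) next
      if (segments$n_het[k] >= 50L) next
      r_l <- segments$somatic_ratio[k - 1L]
      r_r <- segments$somatic_ratio[k + 1L]
      if (abs(r_l - r_r) < T &&
          abs(segments$somatic_ratio[k] - (r_l + r_r) / 2) < 3 * T)
        return(k)
    }
    0L
  }
  repeat {
    segments <- ratio_merge(segments)
    k <- find_blip(segments)
    if (k == 0L) break
    segments <- merge_into(segments, k + 1L, k)
    segments <- merge_into(segments, k, k - 1L)
  }
  rownames(segments) <- NULL
  if (!is.null(segments$somatic_copy_level))
    segments$somatic_copy_level <- 2 * segments$somatic_ratio
  segments
}
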