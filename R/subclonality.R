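#' @name subclonality
#' @title Hypothesis-testing based subclonality characterization
#' @description Each aberrant segment is tested for consistency with a
#'   clonal change of exactly one copy of one allele.  Multi-copy events
#'   cannot be resolved from the somatic ratio alone (a 5-copy gain in 30%
#'   of cancer cells, a 4-copy gain in 45% and a 3-copy gain in 90% share
#'   the adjusted ratio 1.45), so the test is restricted to one-copy
#'   gains/losses and the subclonal fraction is the linear interpolation
#'   between the normal total copy and the one-copy target.
NULL

#' Allelic copy numbers of a segment in the normal sample
#'
#' Splits the total copy `2 R` by the germline allelic balance:
#' `nB = round(2 R laf_g)`, `nA = round(2 R (1 - laf_g))`.
#'
#' @param R GC-corrected read-count ratio of the segment in the normal
#'   sample.
#' @param laf_g median germline LAF on the segment (het sites), in
#'   \[0, 0.5\].
#' @return Integer vector `c(nA, nB)` with `nA >= nB`.
#' @examples
#' normal_allelic_copy(1, 0.5)    # 1 1
#' normal_allelic_copy(1.5, 1/3)  # 2 1
#' @export
normal_allelic_copy <- function(R, laf_g) {
  stopifnot(R > 0, laf_g >= 0, laf_g <= 0.5)
  c(nA = as.integer(round(2 * R * (1 - laf_g))),
    nB = as.integer(round(2 * R * laf_g)))
}

#' Test a segment for a clonal one-copy change
#'
#' If the admixture-adjusted somatic ratio exceeds 1 a one-copy gain is
#' tested (theoretical clonal ratio `(nA + nB + 1)/(nA + nB)`), otherwise a
#' one-copy loss (`(nA + nB - 1)/(nA + nB)`).  Under the null the observed
#' clonal copy-number ratio is `Normal(r_clonal, sigma^2)`; the two-sided
#' p-value is the probability of a ratio at least as extreme as observed.
#' Segments with p below `p_cutoff` depart from the clonal one-copy model
#' and are classified subclonal.  Adjusted ratios within `neutral_band` of
#' 1 are declared copy-neutral and not tested (most false-positive
#' subclonal calls are misclassified copy-neutral segments).
#'
#' @param r_adj admixture-adjusted somatic ratio.
#' @param nA,nB allelic copy numbers in the normal sample.
#' @param sigma null SD of the ratio estimate (see [bootstrap_ratio_sd()]).
#' @param p_cutoff significance threshold (default 0.05).
#' @param neutral_band half-width of the copy-neutral guard band
#'   (default 0.05).
#' @return list with `direction` (`"gain"`, `"loss"` or `"neutral"`),
#'   `r_clonal`, `p_value`, `classification` (`"clonal"`, `"subclonal"` or
#'   `"neutral"`).
#' @export
test_one_copy_clonal <- function(r_adj, nA, nB, sigma, p_cutoff = 0.05,
                                 neutral_band = 0.05) {
  stopifnot(sigma > 0, nA + nB >= 0)
  if (abs(r_adj - 1) <= neutral_band)
    return(list(direction = "neutral", r_clonal = 1, p_value = NA_real_,
                classification = "neutral"))
  tot <- nA + nB
  if (tot < 1) stop("segment with zero copies in the normal sample")
  direction <- if (r_adj > 1) "gain" else "loss"
  if (direction == "loss" && tot == 1)
    stop("cannot test one-copy loss below zero copies")
  r_clonal <- if (direction == "gain") (tot + 1) / tot else (tot - 1) / tot
  p <- 2 * pnorm(-abs(r_adj - r_clonal) / sigma)
  list(direction = direction, r_clonal = r_clonal, p_value = p,
       classification = if (p < p_cutoff) "subclonal" else "clonal")
}

#' Subclonal fraction of a one-copy change
#'
#' The target tumor allelic copies `(nA_t, nB_t)` are the one-copy-changed
#' pair implied by the test direction and the tumor LAF: a LAF that moved
#' toward 0.5 means the lesser allele gained (or the greater allele was
#' lost); ties change the lesser allele.  The fraction of tumor cells
#' carrying the change is the linear interpolation
#' `f = (2 r_adj - (nA + nB)) / ((nA_t + nB_t) - (nA + nB))`, clipped to
#' \[0, 1\].
#'
#' @param r_adj admixture-adjusted somatic ratio.
#' @param nA,nB normal-sample allelic copies.
#' @param direction `"gain"` or `"loss"` from [test_one_copy_clonal()].
#' @param laf_t median tumor LAF on the segment.
#' @param laf_g median germline LAF on the segment.
#' @return list with `f`, `f_raw` (unclipped), `nA_t`, `nB_t`.
#' @examples
#' subclonal_fraction(1.45, 1, 1, "gain", 0.45, 0.5)$f  # 0.9
#' @export
subclonal_fraction <- function(r_adj, nA, nB, direction, laf_t, laf_g) {
  stopifnot(direction %in% c("gain", "loss"))
  toward <- laf_t >= laf_g            # LAF moved toward 0.5 (tie -> lesser)
  if (direction == "gain") {
    if (toward) { nA_t <- nA; nB_t <- nB + 1L }
    else { nA_t <- nA + 1L; nB_t <- nB }
  } else {
    if (toward) { nA_t <- nA - 1L; nB_t <- nB }
    else { nA_t <- nA; nB_t <- nB - 1L }
  }
  f_raw <- (2 * r_adj - (nA + nB)) / ((nA_t + nB_t) - (nA + nB))
  if (f_raw < 0 || f_raw > 1)
    message("implied subclonal fraction ", signif(f_raw, 4),
            " outside [0, 1]; one-copy model misfit")
  list(f = min(max(f_raw, 0), 1), f_raw = f_raw,
       nA_t = as.integer(nA_t), nB_t = as.integer(nB_t))
}

#' Expected admixture-adjusted ratio of a subclonal aberration
#'
#' Forward model used by the simulator and tests: a subclone at integer
#' copy `c` present in fraction `f` of the cancer cells (the rest diploid)
#' has adjusted ratio `r = (f c + (1 - f) 2)/2`.
#'
#' @param c integer copy number of the subclone.
#' @param f fraction of cancer cells carrying it, in \[0, 1\].
#' @return Expected adjusted somatic ratio.
#' @examples
#' expected_subclonal_ratio(5, 0.30)  # 1.45
#' expected_subclonal_ratio(4, 0.45)  # 1.45
#' @export
expected_subclonal_ratio <- function(c, f) {
  stopifnot(all(c >= 0), all(f >= 0 & f <= 1))
  (f * c + (1 - f) * 2) / 2
}

#' Bootstrap SD of the segment somatic-ratio estimate
#'
#' Nonparametric bootstrap over the segment's SNP pairs of the
#' Geary-Hinkley MLE, used as the null SD in [test_one_copy_clonal()].
#' For large segments the resample size is capped at `max_snps` and the SD
#' rescaled by `sqrt(m/n)` (m-out-of-n bootstrap).
#'
#' @param rd_t,rd_n paired depths of the segment's SNPs.
#' @param n_boot number of resamples (default 200).
#' @param max_snps resample-size cap (default 800).
#' @param min_sigma lower floor on the returned SD.
#' @param seed integer seed.
#' @return Estimated SD of the ratio estimator (scalar > 0).
#' @export
bootstrap_ratio_sd <- function(rd_t, rd_n, n_boot = 200L, max_snps = 800L,
                               min_sigma = 1e-4, seed = 1L) {
  keep <- rd_n > 0
  rd_t <- rd_t[keep]; rd_n <- rd_n[keep]
  n <- length(rd_t)
  if (n < 3L) return(max(0.2, min_sigma))
  m <- min(n, max_snps)
  r0 <- estimate_somatic_ratio(rd_t, rd_n)
  lo <- max(0.01, r0 - 0.5); hi <- r0 + 0.5
  est <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, m, replace = TRUE)
      xt <- rd_t[idx]; xn <- rd_n[idx]
      .golden_max(function(r) cpp_gh_loglik(xt, xn, r), lo, hi)
    }, numeric(1))
  })
  max(sd(est) * sqrt(m / n), min_sigma)
}

#' Characterize subclonality for every segment
#'
#' Applies the neutral guard band, the one-copy clonal test and the
#' subclonal-fraction computation to each segment, and labels aberration
#' events (gain, loss, LOH, copy-neutral LOH).  A segment is reported
#' subclonal only when the test rejects AND the implied fraction lies
#' strictly inside (0, 1); clonal multi-copy events (e.g. a double
#' deletion, implied f = 2) otherwise masquerade as subclonal.
#'
#' @param segments segment table with `somatic_ratio`, `snp_first`,
#'   `snp_last`.
#' @param snps SNP table (sorted as indexed by the segments) with `rd_n`,
#'   `rd_t_use`/`rd_t`, `laf_t`, `laf_n`, `geno`, `ratio_n`.
#' @param alpha admixture rate used for adjustment.
#' @param cfg configuration from [scna_config()].
#' @param seed integer seed for the bootstrap.
#' @return The segment table with columns `r_adj`, `nA`, `nB`, `direction`,
#'   `r_clonal`, `sigma`, `p_value`, `classification`, `f`, `nA_t`, `nB_t`,
#'   `event` appended.
#' @export
characterize_subclonality <- function(segments, snps, alpha,
                                      cfg = scna_config(), seed = cfg$seed) {
  sc <- cfg$subclonality
  segments <- as.data.frame(segments)
  nseg <- nrow(segments)
  rd_t <- if (!is.null(snps$rd_t_use)) snps$rd_t_use else snps$rd_t
  rd_n <- snps$rd_n
  ratio_n <- if (!is.null(snps$ratio_n)) snps$ratio_n
             else rd_n / median(rd_n)
  out <- data.frame(
    r_adj = adjust_somatic_ratio(segments$somatic_ratio, alpha),
    nA = NA_integer_, nB = NA_integer_, direction = "neutral",
    r_clonal = NA_real_, sigma = NA_real_, p_value = NA_real_,
    classification = "neutral", f = NA_real_, nA_t = NA_integer_,
    nB_t = NA_integer_, event = "neutral")
  for (k in seq_len(nseg)) {
    idx <- segments$snp_first[k]:segments$snp_last[k]
    het <- idx[snps$geno[idx] == "het"]
    laf_g <- if (length(het)) median(snps$laf_n[het]) else 0.5
    R <- median(ratio_n[idx])
    nab <- normal_allelic_copy(max(R, 0.25), laf_g)
    out$nA[k] <- nab["nA"]; out$nB[k] <- nab["nB"]
    r_adj <- out$r_adj[k]
    laf_t <- if (length(het)) median(snps$laf_t[het]) else 0.5
    if (abs(r_adj - 1) <= sc$neutral_band) {
      # copy-neutral LOH: total copy unchanged but het LAF collapsed toward
      # the admixture floor alpha/2; split the difference with 0.5
      if (length(het) >= 5L && nab["nA"] == 1L && nab["nB"] == 1L &&
          laf_t < (0.5 + alpha / 2) / 2) {
        out$nA_t[k] <- 2L; out$nB_t[k] <- 0L
        out$direction[k] <- "neutral"
        out$classification[k] <- "clonal"
        out$f[k] <- 1
        out$event[k] <- "cnLOH"
      }
      next
    }
    tot <- nab["nA"] + nab["nB"]
    if (tot < 1 || (r_adj < 1 && tot == 1)) next
    sigma <- bootstrap_ratio_sd(rd_t[idx], rd_n[idx], n_boot = sc$n_boot,
                                max_snps = sc$boot_max_snps,
                                min_sigma = sc$min_sigma,
                                seed = seed + k)
    # adjustment rescales the estimate, so its SD scales the same way
    sigma_adj <- sigma / (1 - alpha)
    tst <- test_one_copy_clonal(r_adj, nab["nA"], nab["nB"], sigma_adj,
                                p_cutoff = sc$p_cutoff,
                                neutral_band = sc$neutral_band)
    out$direction[k] <- tst$direction
    out$r_clonal[k] <- tst$r_clonal
    out$sigma[k] <- sigma_adj
    out$p_value[k] <- tst$p_value
    fr <- subclonal_fraction(r_adj, nab["nA"], nab["nB"], tst$direction,
                             laf_t, laf_g)
    if (tst$classification == "subclonal" &&
        fr$f_raw > 0 && fr$f_raw < 1) {
      # departs from the one-copy clonal model with a feasible fraction
      out$classification[k] <- "subclonal"
      out$f[k] <- fr$f
      out$nA_t[k] <- fr$nA_t; out$nB_t[k] <- fr$nB_t
    } else if (fr$f_raw >= 0 && fr$f_raw <= 1) {
      # consistent with a clonal one-copy change
      out$classification[k] <- "clonal"
      out$f[k] <- 1
      out$nA_t[k] <- fr$nA_t; out$nB_t[k] <- fr$nB_t
    } else {
      # clonal multi-copy event: integer copies from the adjusted ratio,
      # lesser-allele copies recovered from the mixed tumor LAF
      out$classification[k] <- "clonal"
      out$f[k] <- 1
      tot_t <- max(0L, as.integer(round(2 * r_adj)))
      b_mix <- laf_t * 2 * segments$somatic_ratio[k]
      b_t <- if (alpha < 1) (b_mix - alpha) / (1 - alpha) else 0
      nB_t <- min(max(as.integer(round(b_t)), 0L), tot_t)
      out$nA_t[k] <- tot_t - nB_t; out$nB_t[k] <- nB_t
    }
    tot_t <- out$nA_t[k] + out$nB_t[k]
    out$event[k] <- if (min(out$nA_t[k], out$nB_t[k]) == 0 && tot_t == 2)
        "cnLOH"
      else if (min(out$nA_t[k], out$nB_t[k]) == 0 && tot_t >= 1) "LOH"
      else if (tst$direction == "gain") "gain" else "loss"
  }
  cbind(segments, out)
}
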