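#' @name segmentation
#' @title Change-point detection on heterozygous-site LAF
#' @description Candidate change points are over-detected by circular binary
#'   segmentation (CBS) run on the LAF sequence padded with pseudo points,
#'   then pruned by forward stepwise selection with BIC on the
#'   piecewise-constant change-point model.
NULL

# run a block of code under a temporary, seeded RNG state
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# 1 - alpha Monte-Carlo quantile of the scan statistic under an i.i.d.
# normal null, cached per (bucketed length, alpha, scan geometry).
# Used in place of permutations for long sequences; seeded independently
# of the user RNG so results are session-stable.
null_max_t_quantile <- function(n, alpha, wmax, grid_target,
                                min_width = 3L, nrep = 100L) {
  bucket <- as.integer(round(exp(round(log(n) / log(1.4)) * log(1.4))))
  key <- paste(bucket, alpha, wmax, grid_target, min_width, nrep,
               sep = "_")
  hit <- .scna_cache[[key]]
  if (!is.null(hit)) return(hit)
  seed <- 190000L + (bucket %% 100000L)
  vals <- cpp_null_max_t(bucket, nrep, wmax, grid_target, seed, min_width)
  q <- as.numeric(quantile(vals, 1 - alpha, names = FALSE))
  .scna_cache[[key]] <- q
  q
}

# recursive CBS on x[seq]; returns change-point indices (cp between k, k+1)
.cbs_recurse <- function(x, l, r, alpha, nperm, perm_nmax, wmax, grid_target,
                         min_width, seed_base, t_hard = 7) {
  n <- r - l + 1L
  if (n < 4L) return(integer(0))
  seg <- x[l:r]
  hit <- cpp_max_t(seg, wmax, grid_target, min_width)
  if (hit$t <= 0) return(integer(0))
  sig <- if (hit$t >= t_hard) {
    TRUE
  } else if (n <= perm_nmax) {
    p <- cpp_perm_pval(seg, hit$t, nperm, alpha, wmax, grid_target,
                       seed_base + l %% 10000L, min_width)
    p < alpha
  } else {
    hit$t > null_max_t_quantile(n, alpha, wmax, grid_target, min_width)
  }
  if (!sig) return(integer(0))
  i_abs <- l - 1L + hit$i          # cp before arc (0 = segment start)
  j_abs <- l - 1L + hit$j          # cp at arc end (n = segment end)
  cps <- integer(0)
  bounds <- l - 1L                 # segment-internal breakpoints
  if (hit$i > 0L) { cps <- c(cps, i_abs); bounds <- c(bounds, i_abs) }
  if (hit$j < n) { cps <- c(cps, j_abs); bounds <- c(bounds, j_abs) }
  bounds <- c(bounds, r)
  for (k in seq_len(length(bounds) - 1L)) {
    cps <- c(cps, .cbs_recurse(x, bounds[k] + 1L, bounds[k + 1L], alpha,
                               nperm, perm_nmax, wmax, grid_target,
                               min_width, seed_base, t_hard))
  }
  sort(unique(cps))
}

#' Over-detect change points by padded circular binary segmentation
#'
#' Runs recursive CBS (maximal circular two-sample t statistic with
#' permutation p-values) on the LAF sequence prolonged with `pad_n` pseudo
#' points at each end drawn from a normal distribution with the sequence's
#' mean and SD; the padding controls boundary variance on chromosomes
#' without obvious change points.  Change points falling inside the padding
#' are discarded and the rest are shifted back to original coordinates.
#' For segments longer than `perm_nmax` the permutation test is replaced by
#' a seeded Monte-Carlo null quantile of the same scan statistic.
#'
#' @param x numeric LAF sequence (typically smoothed, het sites only).
#' @param alpha significance level for accepting a split (default 0.01).
#' @param nperm number of permutations (default 1000).
#' @param pad_n pseudo points per end (default 100).
#' @param seed integer seed for padding draws and permutations.
#' @param perm_nmax,wmax,grid_target scan-geometry controls, see
#'   [scna_config()].
#' @return Sorted integer vector of change-point indices `c`, each meaning
#'   a boundary between `x[c]` and `x[c + 1]`; possibly empty.
#' @export
cbs_overdetect <- function(x, alpha = 0.01, nperm = 1000L, pad_n = 100L,
                           seed = 1L, perm_nmax = 1000L, wmax = 256L,
                           grid_target = 512L, min_width = 3L) {
  n <- length(x)
  if (n < 10L) return(integer(0))
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(integer(0))
  padded <- with_local_seed(seed, {
    c(rnorm(pad_n, mean(x), s), x, rnorm(pad_n, mean(x), s))
  })
  cps <- .cbs_recurse(padded, 1L, length(padded), alpha, nperm, perm_nmax,
                      wmax, grid_target, min_width, seed_base = seed)
  cps <- cps - pad_n
  sort(unique(cps[cps >= 1L & cps <= n - 1L]))
}

#' Prune change points by stepwise selection with BIC
#'
#' Models the LAF sequence as piecewise constant: taking cumulative sums on
#' both sides turns each candidate change point `psi_j` into a hinge
#' regressor `(t - psi_j)+` with coefficient equal to the mean shift.
#' Candidates enter by forward stepwise selection, each step adding the
#' candidate whose mean-shift regressor most reduces the model residual
#' (ties toward the leftmost genomic position); the path prefix minimizing
#' BIC is returned.  Selection never invents change points: the result is
#' a subset of `cps`.
#'
#' @param x numeric LAF sequence (same one given to [cbs_overdetect()]).
#' @param cps integer vector of candidate change-point indices.
#' @param bic_variant `"cumseg"` (default; penalty `k log(n) log(log n)`,
#'   the inflated-penalty criterion recommended for change-point selection,
#'   where the classical penalty is known to overfit) or `"classic"`
#'   (`k log n`).
#' @return Sorted integer vector, a subset of `cps`.
#' @export
lars_bic_prune <- function(x, cps, bic_variant = c("cumseg", "classic")) {
  bic_variant <- match.arg(bic_variant)
  cps <- sort(unique(as.integer(cps)))
  K <- length(cps)
  if (K == 0L) return(integer(0))
  n <- length(x)
  stopifnot(all(cps >= 1L & cps <= n - 1L))
  # RSS of the piecewise-constant fit of x with a given change-point set;
  # the cumulative design orders the path, the original-scale fit scores it
  # (the cumulative residuals are integrated noise, whose RSS is not the
  # likelihood the BIC penalty was derived for)
  Sx <- c(0, cumsum(x))
  Sxx <- c(0, cumsum(x^2))
  rss_pc <- function(active_cps) {
    b <- c(0L, sort(active_cps), n)
    len <- diff(b)
    segsum <- Sx[b[-1L] + 1L] - Sx[b[-length(b)] + 1L]
    segss <- Sxx[b[-1L] + 1L] - Sxx[b[-length(b)] + 1L]
    sum(segss - segsum^2 / len)
  }
  # forward stepwise: at each step add the candidate whose mean-shift
  # regressor most reduces the model residual (ties -> leftmost genomic
  # position).  Ordering by raw correlation with the cumulative residual
  # -- the literal LARS entry order on the hinge design -- misorders
  # candidates when the detrended cumulative residual is tent-shaped, so
  # the entry criterion is the residual reduction of the model itself.
  active <- integer(0)
  path <- integer(0)
  rss <- numeric(K + 1L)
  rss[1L] <- rss_pc(integer(0))
  for (step in seq_len(K)) {
    remaining <- setdiff(seq_len(K), active)
    gain <- vapply(remaining, function(j) rss_pc(cps[c(active, j)]),
                   numeric(1))
    pick <- remaining[which.min(gain)]
    active <- c(active, pick)
    path <- c(path, pick)
    rss[step + 1L] <- rss_pc(cps[active])
  }
  k_seq <- 0:K
  Cn <- if (bic_variant == "cumseg") log(log(max(n, 8))) else 1
  bic <- n * log(pmax(rss, 1e-12) / n) + k_seq * log(n) * Cn
  k_best <- k_seq[which.min(bic)]
  sort(cps[path[seq_len(k_best)]])
}

#' Segment one chromosome's heterozygous LAF sequence
#'
#' Smooths the LAF signal, over-detects change points with padded CBS and
#' prunes them with BIC.  Breakpoint base-pair coordinates are placed midway
#' between the flanking heterozygous sites.
#'
#' @param pos positions (bp) of the heterozygous sites, sorted.
#' @param laf LAF values at those sites.
#' @param cfg configuration from [scna_config()].
#' @param seed integer seed.
#' @return data.frame with columns `start`, `end` (half-open, 0-based start),
#'   `first_idx`, `last_idx` (het-site index range), `n_het`, `mean_laf`.
#' @export
segment_chromosome <- function(pos, laf, cfg = scna_config(), seed = cfg$seed) {
  n <- length(laf)
  stopifnot(length(pos) == n)
  sm <- cfg$smoothing; sg <- cfg$segmentation
  if (n >= sg$min_het) {
    x <- smooth_laf(laf, sm$half_width, sm$t)
    cps <- cbs_overdetect(x, alpha = sg$alpha, nperm = sg$nperm,
                          pad_n = sg$pad_n, seed = seed,
                          perm_nmax = sg$perm_nmax, wmax = sg$wmax,
                          grid_target = sg$grid_target,
                          min_width = sg$min_width)
    cps <- lars_bic_prune(x, cps, sg$bic_variant)
  } else {
    cps <- integer(0)
  }
  first <- c(1L, cps + 1L)
  last <- c(cps, n)
  bp <- if (length(cps)) floor((pos[cps] + pos[cps + 1L]) / 2) else numeric(0)
  data.frame(
    start = c(pos[1L] - 1L, bp),
    end = c(bp, pos[n]),
    first_idx = first, last_idx = last,
    n_het = last - first + 1L,
    mean_laf = vapply(seq_along(first),
                      function(k) mean(laf[first[k]:last[k]]), numeric(1)))
}
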