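#' @name admixture
#' @title Copy-state assignment and admixture-rate estimation
#' @description Somatic copy levels (2 x somatic ratio) of clonal segments
#'   cluster at discrete levels shifted toward 2 by the intermixed normal
#'   cells.  A finite Gaussian mixture (component count chosen by AIC)
#'   models the levels; a Markov chain Monte Carlo sampler allocates each
#'   segment to a component; components are mapped to integer copies with
#'   the component nearest level 2 anchored at copy 2; and the admixture
#'   rate is the weighted least-squares solution explaining the shift of
#'   clonal segments from integer levels.
NULL

#' Expected somatic ratio of a clonal copy-number state under admixture
#'
#' A clonal segment with integer tumor copy number `c` in a sample with
#' normal-cell fraction `alpha` has expected somatic copy level
#' `2 alpha + (1 - alpha) c`, hence ratio `r = (2 alpha + (1 - alpha) c)/2`.
#' `r(2, alpha) = 1` for every alpha: ratio 1 anchors integer copy 2.
#'
#' @param c integer copy number (>= 0).
#' @param alpha admixture rate in \[0, 1).
#' @return Expected somatic ratio.
#' @examples
#' expected_somatic_ratio(3, 0.4)   # 1.3
#' expected_somatic_ratio(0:4, 0.4) # 0.4 0.7 1.0 1.3 1.6
#' @export
expected_somatic_ratio <- function(c, alpha) {
  stopifnot(all(c >= 0), all(alpha >= 0 & alpha < 1))
  (2 * alpha + (1 - alpha) * c) / 2
}

#' Adjust an observed somatic ratio for the admixture rate
#'
#' Inverse of [expected_somatic_ratio()] on the ratio scale:
#' `r_adj = (r - alpha) / (1 - alpha)`, the ratio that would be observed in
#' a pure tumor sample.
#'
#' @param r observed somatic ratio.
#' @param alpha admixture rate in \[0, 1).
#' @return Adjusted ratio.
#' @export
adjust_somatic_ratio <- function(r, alpha) (r - alpha) / (1 - alpha)

# weighted 1-D Gaussian EM with shared variance; returns NULL on failure.
# Several starts (quantile, k-means-style, jittered) guard against local
# optima when outer clusters hold few segments.
.em_gauss <- function(x, w, K, iters = 200L, tol = 1e-8) {
  starts <- list(
    as.numeric(quantile(x, probs = (seq_len(K) - 0.5) / K, names = FALSE)),
    tryCatch(with_local_seed(1234L,
               sort(stats::kmeans(x, centers = K, nstart = 5,
                                  iter.max = 50)$centers[, 1])),
             error = function(e) NULL),
    as.numeric(quantile(x, probs = seq(0.02, 0.98, length.out = K),
                        names = FALSE)))
  best <- NULL
  for (mu0 in starts) {
    if (is.null(mu0)) next
    fit <- .em_gauss_once(x, w, mu0, iters, tol)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  best
}

.em_gauss_once <- function(x, w, mu, iters = 200L, tol = 1e-8) {
  n <- length(x)
  K <- length(mu)
  mu <- mu + seq_len(K) * 1e-9          # break exact ties
  s2 <- max(var(x) / K^2, 1e-6)
  pi_k <- rep(1 / K, K)
  w <- w / sum(w) * n
  ll_old <- -Inf
  for (it in seq_len(iters)) {
    d <- vapply(seq_len(K),
                function(k) pi_k[k] * dnorm(x, mu[k], sqrt(s2)), numeric(n))
    rowsum_d <- rowSums(d)
    if (any(rowsum_d <= 0) || any(!is.finite(rowsum_d))) return(NULL)
    g <- d / rowsum_d
    ll <- sum(w * log(rowsum_d))
    nk <- colSums(w * g)
    if (any(nk < 1e-9)) return(NULL)
    mu <- colSums(w * g * x) / nk
    s2 <- max(sum(w * g * (x - rep(mu, each = n))^2) / sum(nk), 1e-6)
    pi_k <- nk / sum(nk)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  ord <- order(mu)
  list(mu = mu[ord], pi = pi_k[ord], s2 = s2, loglik = ll,
       n_par = 2 * K)  # K means + (K-1) props + shared variance
}

#' Choose the number of mixture components for the copy-level histogram
#'
#' Fits Gaussian mixtures with `K = k_min..k_max` components to the somatic
#' copy levels by (weighted) EM and selects `K` by AIC, rejecting any
#' solution whose adjacent centers are closer than `min_gap` (0.2
#' corresponds to the 80% normal-contamination cap).  The minimum is 3
#' components: no change, one copy loss, one copy gain.
#'
#' @param levels somatic copy levels (2 x ratio), one per segment.
#' @param weights non-negative segment weights (e.g. SNP counts); equal by
#'   default.
#' @param k_min,k_max component-count range (defaults 3, 8).
#' @param min_gap minimum distance between component centers (default 0.2).
#' @return list with `K`, sorted `centers`, mixing proportions `pi`, shared
#'   variance `s2`.
#' @export
select_component_count <- function(levels, weights = NULL, k_min = 3L,
                                   k_max = 8L, min_gap = 0.2) {
  stopifnot(length(levels) >= 1)
  if (is.null(weights)) weights <- rep(1, length(levels))
  if (length(levels) < 3L || sd(levels) < min_gap / 4) {
    s0 <- median(levels)
    return(list(K = 3L, centers = c(s0 - 1, s0, s0 + 1),
                pi = rep(1 / 3, 3), s2 = 1e-4, degenerate = TRUE))
  }
  k_max <- min(k_max, length(unique(levels)))
  # merge any pair of centers closer than min_gap (pi-weighted mean) so the
  # overfitting guard never discards an otherwise good solution
  enforce_gap <- function(mu, pi_k) {
    while (length(mu) > 1L && min(diff(mu)) < min_gap) {
      i <- which.min(diff(mu))
      w2 <- pi_k[i] + pi_k[i + 1L]
      mu[i] <- (mu[i] * pi_k[i] + mu[i + 1L] * pi_k[i + 1L]) / w2
      pi_k[i] <- w2
      mu <- mu[-(i + 1L)]; pi_k <- pi_k[-(i + 1L)]
    }
    list(mu = mu, pi = pi_k)
  }
  wn <- weights / sum(weights) * length(levels)
  best <- NULL; best_aic <- Inf
  for (K in seq.int(k_min, max(k_min, k_max))) {
    fit <- .em_gauss(levels, weights, K)
    if (is.null(fit)) next
    m <- enforce_gap(fit$mu, fit$pi)
    Ke <- length(m$mu)
    dens <- vapply(seq_len(Ke),
                   function(k) m$pi[k] * dnorm(levels, m$mu[k], sqrt(fit$s2)),
                   numeric(length(levels)))
    ll <- sum(wn * log(pmax(rowSums(as.matrix(dens)), 1e-300)))
    aic <- -2 * ll + 2 * (2 * Ke)
    if (aic < best_aic) {
      best_aic <- aic
      best <- list(K = Ke, centers = m$mu, pi = m$pi, s2 = fit$s2)
    }
  }
  if (is.null(best)) {
    s0 <- median(levels)
    return(list(K = 3L, centers = c(s0 - 1, s0, s0 + 1),
                pi = rep(1 / 3, 3), s2 = 1e-4, degenerate = TRUE))
  }
  if (best$K < 3L) {
    # pad flanking one-copy levels so loss/no-change/gain are representable
    step <- max(min_gap, 0.5)
    mu <- best$centers
    best$centers <- sort(unique(c(mu, min(mu) - step, max(mu) + step)))
    best$pi <- rep(1 / length(best$centers), length(best$centers))
    best$K <- length(best$centers)
  }
  list(K = best$K, centers = best$centers, pi = best$pi, s2 = best$s2,
       degenerate = FALSE)
}

#' Map mixture components to integer copy numbers
#'
#' Components are placed on the integer-copy lattice
#' `level(c) = 2 alpha + (1 - alpha) c` anchored at ratio 1 <-> copy 2.
#' Candidate admixture rates are generated by hypothesizing a small integer
#' copy (0-6) for each component; a candidate is rejected when any center
#' falls below the double-deletion floor `2 alpha` (no signal can drop
#' below the pure-normal contribution), which eliminates half-step
#' harmonics.  Among the remaining candidates the mass-weighted capped
#' squared lattice misfit is minimized (ties toward less contamination).
#' Components left far from the chosen lattice (residual beyond `band`)
#' are subclonal-level components; their residuals are returned in the
#' `"resid"` attribute so callers can exclude their segments from
#' admixture estimation.
#'
#' @param centers sorted component centers (copy-level scale).
#' @param weights component masses (mixing proportions or segment counts);
#'   equal by default.
#' @param max_alpha largest admixture rate considered (default 0.8).
#' @param band lattice-misfit cap (default 0.15 copy-level units).
#' @return Integer copy number per component, with attributes `"resid"`
#'   (signed lattice residual per component) and `"alpha0"` (the mapping's
#'   internal admixture estimate).
#' @export
map_copy_states <- function(centers, weights = NULL, max_alpha = 0.8,
                            band = 0.15) {
  K <- length(centers)
  if (is.null(weights)) weights <- rep(1, K)
  weights <- weights / sum(weights)
  if (K == 1L) {
    out <- 2L
    attr(out, "resid") <- 0
    attr(out, "alpha0") <- 0
    return(out)
  }
  cands <- 0
  for (k in seq_len(K)) {
    for (cc in c(0:1, 3:6)) {
      a <- (centers[k] - cc) / (2 - cc)
      if (is.finite(a) && a >= 0 && a <= max_alpha) cands <- c(cands, a)
    }
  }
  cands <- sort(unique(round(cands, 6)))
  floor_ok <- cands <= (min(centers) + band) / 2
  cands <- cands[floor_ok]
  if (!length(cands)) cands <- 0
  best <- NULL; best_loss <- Inf; best_a <- 0
  for (a in cands) {
    step <- 1 - a
    cp <- as.integer(round((centers - 2 * a) / step))
    cp <- pmax(cp, 0L)
    resid <- centers - (2 * a + step * cp)
    # hair-thin parsimony term: breaks exact ties toward less
    # contamination without ever overriding the data
    loss <- sum(weights * pmin(resid^2, band^2)) + 1e-4 * a
    if (loss < best_loss - 1e-12 ||
        (abs(loss - best_loss) <= 1e-12 && a < best_a)) {
      best_loss <- loss; best <- list(cp = cp, resid = resid); best_a <- a
    }
  }
  out <- cummax(best$cp)   # monotone in center order
  attr(out, "resid") <- best$resid
  attr(out, "alpha0") <- best_a
  out
}

#' Allocate segments to copy states by Markov chain Monte Carlo
#'
#' Bayesian finite mixture: each somatic copy level belongs to one of `K`
#' normal components centered at the discrete levels with variance
#' `hyper_var` (0.01 allows clonal levels to shift about 0.1 from integer
#' positions); allocations are multinomial with a conjugate Dirichlet prior
#' on the mixing weights.  The chain sweeps single-segment reassignments
#' from their full conditional (acceptance probability 1) alternating with
#' a Dirichlet draw of the weights.  The per-segment posterior is the
#' fraction of kept iterations spent in the modal state.
#'
#' @param levels somatic copy levels, one per segment.
#' @param centers component centers (sorted).
#' @param hyper_var component variance (default 0.01).
#' @param iters,burn_in chain length and burn-in (defaults 10000, 2000).
#' @param dirichlet Dirichlet concentration (default 1).
#' @param seed integer seed (chain is bit-reproducible given the seed).
#' @return list with `state` (component index per segment), `copy`
#'   (mapped integer copies per segment), `posterior` (modal-state
#'   frequency), `centers`, `copies` (per component).
#' @export
mh_assign <- function(levels, centers, hyper_var = 0.01, iters = 10000L,
                      burn_in = 2000L, dirichlet = 1, seed = 1L) {
  J <- length(levels); K <- length(centers)
  stopifnot(K >= 1, iters > burn_in)
  loglik <- vapply(seq_len(K),
                   function(k) dnorm(levels, centers[k], sqrt(hyper_var),
                                     log = TRUE), numeric(J))  # J x K
  counts <- matrix(0L, J, K)
  with_local_seed(seed, {
    # init from likelihood alone
    z <- max.col(loglik)
    for (it in seq_len(iters)) {
      nk <- tabulate(z, K)
      gshape <- dirichlet + nk
      pi_k <- rgamma(K, gshape)
      pi_k <- pi_k / sum(pi_k)
      lp <- sweep(loglik, 2L, log(pi_k), "+")
      m <- lp - apply(lp, 1L, max)
      p <- exp(m); p <- p / rowSums(p)
      # inverse-CDF draw per segment, vectorized over J
      u <- runif(J)
      cum <- p %*% upper.tri(diag(K), diag = TRUE)
      z <- pmin(rowSums(u > cum) + 1L, K)
      if (it > burn_in) counts[cbind(seq_len(J), z)] <-
          counts[cbind(seq_len(J), z)] + 1L
    }
  })
  kept <- iters - burn_in
  state <- max.col(counts, ties.method = "first")
  posterior <- counts[cbind(seq_len(J), state)] / kept
  copies <- map_copy_states(centers, weights = tabulate(state, K) + 0.5)
  list(state = state, copy = as.integer(copies)[state],
       posterior = posterior, centers = centers,
       copies = as.integer(copies),
       lattice_resid = attr(copies, "resid"),
       alpha0 = attr(copies, "alpha0"))
}

#' Estimate the admixture rate from clonal segments
#'
#' Weighted least squares of the clonal copy-level shift: with expected
#' level `2 alpha + (1 - alpha) c` for clonal copy `c`, the residual
#' `s_j - c_j = alpha (2 - c_j)` gives the closed form
#' `alpha = sum w (2 - c)(s - c) / sum w (2 - c)^2`, clipped to
#' `[0, max_alpha]`.  Segments with copy 2 carry no information; candidate
#' subclonal segments must be excluded by the caller.
#'
#' @param levels clonal somatic copy levels.
#' @param copies assigned integer copies (same length).
#' @param weights segment weights (default equal).
#' @param max_alpha reporting cap (default 0.8).
#' @return Estimated admixture rate.
#' @examples
#' estimate_alpha(c(0.8, 1.4, 2.0, 2.6, 3.2), 0:4)  # 0.4
#' @export
estimate_alpha <- function(levels, copies, weights = NULL, max_alpha = 0.8) {
  stopifnot(length(levels) == length(copies))
  if (is.null(weights)) weights <- rep(1, length(levels))
  u <- 2 - copies
  if (all(u == 0)) {
    warning("all clonal segments have copy 2; admixture rate undefined, ",
            "returning 0")
    return(0)
  }
  a <- sum(weights * u * (levels - copies)) / sum(weights * u^2)
  min(max(a, 0), max_alpha)
}

#' Fit the admixture model to a segment table
#'
#' Convenience wrapper chaining [select_component_count()], [mh_assign()]
#' and [estimate_alpha()]: flags segments with modal posterior below the
#' threshold as candidate subclonal and estimates alpha from the rest.
#'
#' @param segments data.frame with `somatic_ratio` and a weight column
#'   (`n_snps` if present).
#' @param cfg configuration from [scna_config()].
#' @param seed integer seed.
#' @return list with `alpha`, `K`, `centers`, `copies`, and per-segment
#'   vectors `copy_state`, `posterior`, `clonality`.
#' @export
fit_admixture <- function(segments, cfg = scna_config(), seed = cfg$seed) {
  ad <- cfg$admixture
  levels <- 2 * segments$somatic_ratio
  w <- if (!is.null(segments$n_snps)) segments$n_snps
       else rep(1, length(levels))
  # component count from the histogram of levels: one entry per segment
  # (a long neutral chromosome must not drown the aberrant levels)
  sel <- select_component_count(levels, weights = NULL, k_min = ad$k_min,
                                k_max = ad$k_max,
                                min_gap = ad$min_center_gap)
  fit <- mh_assign(levels, sel$centers, hyper_var = ad$hyper_var,
                   iters = ad$iters, burn_in = ad$burn_in,
                   dirichlet = ad$dirichlet, seed = seed)
  # candidate subclonal: ambiguous allocation OR a component sitting off
  # the integer-copy lattice (a subclonal level that earned its own
  # component)
  off_lattice <- abs(fit$lattice_resid) > 0.12
  cand <- fit$posterior < ad$posterior_threshold |
    off_lattice[fit$state]
  clonal <- !cand
  alpha <- if (any(clonal & fit$copy != 2))
    estimate_alpha(levels[clonal], fit$copy[clonal], w[clonal],
                   max_alpha = ad$max_alpha)
  else {
    warning("no informative clonal segments; admixture rate set to 0")
    0
  }
  list(alpha = alpha, K = sel$K, centers = fit$centers, copies = fit$copies,
       copy_state = fit$copy, posterior = fit$posterior,
       clonality = ifelse(cand, "candidate_subclonal", "clonal"))
}
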