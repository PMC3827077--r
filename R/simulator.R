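#' @name simulator
#' @title Cancer-genome simulator and evaluation harness
#' @description Generates paired tumor/normal read-depth + LAF data
#'   following a 7-step protocol: (1) build a template normal genome with
#'   heterozygous sites at realistic spacing, (2) record median and SD of
#'   read depth and lesser-allele counts per 10 kb window, (3) place SCNA
#'   events of varying size/type/subclonality, (4) alter the window medians
#'   by each event's expected somatic ratio, (5) draw event-region counts
#'   from normal distributions with the altered medians and the step-2 SDs,
#'   (6) admix pseudo-cancer and normal counts at rates 0.2/0.4/0.6, and
#'   (7) thin coverage binomially to emulate 40x/20x sequencing.  The
#'   template is synthetic (the study genome used as the original template
#'   is unpublished): het spacing is log-normal with median 453 bp, matching
#'   the printed spacing summary.
NULL

#' Simulator configuration
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param base_coverage mean read depth of the template (default 60).
#' @param window_bp window size for median/SD estimation (default 10000).
#' @param het_meanlog,het_sdlog log-normal parameters of het-site spacing
#'   (defaults give median 453 bp with 1%/99% quantiles bracketing
#'   5-17036 bp).
#' @param hom_density hom sites per het site (default 0.5).
#' @param window_noise_sd SD of multiplicative window-level depth noise
#'   (default 0.1), mimicking non-uniform coverage.
#' @param admixture_rate fraction of normal cells mixed in (default 0.2).
#' @param downsample_to target coverage after thinning (default equals
#'   `base_coverage`, i.e. no thinning).
#' @param seed integer seed.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(chrom_lengths = setNames(rep(1e7, 4),
                                                paste0("chr", 1:4)),
                       base_coverage = 60, window_bp = 1e4,
                       het_meanlog = log(453), het_sdlog = 1.5,
                       hom_density = 0.5, window_noise_sd = 0.1,
                       admixture_rate = 0.2, downsample_to = base_coverage,
                       seed = 1L) {
  stopifnot(downsample_to <= base_coverage, admixture_rate >= 0,
            admixture_rate < 1)
  structure(list(chrom_lengths = chrom_lengths,
                 base_coverage = base_coverage, window_bp = window_bp,
                 het_meanlog = het_meanlog, het_sdlog = het_sdlog,
                 hom_density = hom_density,
                 window_noise_sd = window_noise_sd,
                 admixture_rate = admixture_rate,
                 downsample_to = downsample_to, seed = as.integer(seed)),
            class = "sim_config")
}

# allelic copies (nA, nB) of the four event types; normal het = (1, 1)
.event_copies <- function(type) {
  switch(type,
         double_deletion = c(0L, 0L),
         LOH = c(1L, 0L),
         gain1 = c(2L, 1L),
         gain2 = c(3L, 1L),
         stop("unknown event type: ", type))
}

#' Build the synthetic template normal genome
#'
#' Heterozygous positions are placed by sampling spacings from the
#' log-normal spacing model; homozygous sites are interleaved uniformly at
#' `hom_density` per het site.  Per-site normal read depth is Poisson with
#' window-level multiplicative noise; lesser-allele counts are binomial
#' (p = 0.5 at het sites, a small error rate at hom sites).  Per 10 kb
#' window the median and SD of read depth (all sites) and of het
#' lesser-allele counts are recorded for the tumor-count draws.
#'
#' @param cfg a [sim_config()].
#' @return list with `sites` (data.table: chrom, pos, geno, rd_n, lesser_n,
#'   window id) and `windows` (per-window medians/SDs).
#' @export
make_template_normal <- function(cfg) {
  with_local_seed(cfg$seed, {
    pieces <- lapply(names(cfg$chrom_lengths), function(ch) {
      len <- cfg$chrom_lengths[[ch]]
      n_guess <- ceiling(len / exp(cfg$het_meanlog + cfg$het_sdlog^2 / 2) * 1.4) + 50L
      sp <- pmax(1, round(rlnorm(n_guess, cfg$het_meanlog, cfg$het_sdlog)))
      pos <- cumsum(sp)
      while (pos[length(pos)] < len) {
        sp2 <- pmax(1, round(rlnorm(n_guess, cfg$het_meanlog, cfg$het_sdlog)))
        pos <- c(pos, pos[length(pos)] + cumsum(sp2))
      }
      het_pos <- pos[pos <= len]
      n_hom <- round(length(het_pos) * cfg$hom_density)
      hom_pos <- sort(sample.int(len, n_hom))
      dt <- data.table::data.table(
        chrom = ch,
        pos = c(het_pos, hom_pos),
        geno = rep(c("het", "hom"), c(length(het_pos), n_hom)))
      dt <- dt[order(dt$pos), ]
      dt <- dt[!duplicated(dt$pos), ]
      dt
    })
    sites <- data.table::rbindlist(pieces)
    sites$win <- paste0(sites$chrom, ":", sites$pos %/% cfg$window_bp)
    wfac <- rnorm(length(unique(sites$win)), 1, cfg$window_noise_sd)
    wfac <- pmax(wfac, 0.3)
    names(wfac) <- unique(sites$win)
    lambda <- cfg$base_coverage * wfac[sites$win]
    sites$rd_n <- rpois(nrow(sites), lambda)
    b <- rbinom(nrow(sites), sites$rd_n,
                ifelse(sites$geno == "het", 0.5, 0.005))
    sites$lesser_n <- pmin(b, sites$rd_n - b)

    win_stats <- function(v, subset) {
      s <- split(v[subset], sites$win[subset])
      med <- vapply(s, median, numeric(1))
      sdv <- vapply(s, function(z) if (length(z) > 1) sd(z) else NA_real_,
                    numeric(1))
      list(med = med, sd = sdv)
    }
    het_idx <- sites$geno == "het"
    les_stats <- win_stats(sites$lesser_n, het_idx)
    # the RD median/SD of a 10 kb window pool every covered position
    # (~1e4 values), so they are essentially the generating parameters;
    # the lesser-count stats come from the window's het sites only
    rd_med <- cfg$base_coverage * wfac
    rd_sd <- sqrt(rd_med)
    win_ids <- unique(sites$win)
    les_med_full <- setNames(rep(NA_real_, length(win_ids)), win_ids)
    les_med_full[names(les_stats$med)] <- les_stats$med
    les_sd_full <- setNames(rep(NA_real_, length(win_ids)), win_ids)
    les_sd_full[names(les_stats$sd)] <- les_stats$sd
    windows <- list(
      rd_med = rd_med, rd_sd = rd_sd,
      les_med = les_med_full, les_sd = les_sd_full)
    list(sites = sites[], windows = windows)
  })
}

#' Place SCNA events, mix with normal cells and emit the paired SNP table
#'
#' The pseudo-cancer counts duplicate the template normal counts outside
#' the placed events.  Inside each event the window medians are scaled by
#' the event's expected pure-cancer ratio (subclonal mixing within the
#' tumor), and cancer read depth / lesser-allele counts are drawn from
#' normal distributions with the altered medians and the template window
#' SDs, truncated at zero.  The observed tumor counts then blend cancer
#' and normal counts at the admixture rate.
#'
#' @param template output of [make_template_normal()].
#' @param events data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open bp), `type` (`double_deletion`, `LOH`, `gain1`, `gain2`),
#'   `subclonal_fraction` (1 = clonal).
#' @param cfg the [sim_config()] used for the template.
#' @return list with `snps` (the standard per-SNP table consumed by the
#'   pipeline) and `truth` (the event table with expected ratios appended).
#' @export
place_events_and_mix <- function(template, events, cfg) {
  sites <- data.table::copy(template$sites)
  alpha <- cfg$admixture_rate
  events <- as.data.frame(events)
  if (nrow(events)) {
    ev_by_chr <- split(seq_len(nrow(events)), events$chrom)
    for (ch in names(ev_by_chr)) {
      idx <- ev_by_chr[[ch]]
      o <- idx[order(events$start[idx])]
      if (any(events$start[o][-1] < events$end[o][-length(o)]))
        stop("overlapping events on ", ch)
    }
  }
  n <- nrow(sites)
  # per-site pure-cancer expectations: total-copy ratio (c_cancer/2) and
  # lesser-allele copies b_cancer (normal het carries 1 of 2)
  ratio_cancer <- rep(1, n)
  b_cancer <- rep(1, n)
  in_any <- rep(FALSE, n)
  truth <- events
  truth$copies <- NA_integer_
  truth$expected_ratio <- NA_real_
  for (e in seq_len(nrow(events))) {
    ab <- .event_copies(events$type[e])
    f <- events$subclonal_fraction[e]
    tot_t <- sum(ab)
    c_cancer <- f * tot_t + (1 - f) * 2          # avg copies per cancer cell
    in_ev <- sites$chrom == events$chrom[e] &
      sites$pos > events$start[e] & sites$pos <= events$end[e]
    ratio_cancer[in_ev] <- c_cancer / 2
    b_cancer[in_ev] <- f * ab[2] + (1 - f) * 1
    in_any <- in_any | in_ev
    truth$copies[e] <- tot_t
    truth$expected_ratio[e] <-
      (2 * alpha + (1 - alpha) * c_cancer) / 2
  }
  w <- template$windows
  rd_med <- w$rd_med[sites$win]
  rd_sd <- w$rd_sd[sites$win]
  with_local_seed(cfg$seed + 7919L, {
    # pseudo-cancer counts: duplicated normal outside events, re-drawn
    # from the altered window medians inside
    rd_c <- as.numeric(sites$rd_n)
    lesser_c <- as.numeric(sites$lesser_n)
    idx <- which(in_any)
    rd_c[idx] <- pmax(0, round(rnorm(length(idx),
                                     rd_med[idx] * ratio_cancer[idx],
                                     rd_sd[idx])))
    les_med <- w$les_med[sites$win]
    les_sd <- w$les_sd[sites$win]
    fb <- is.na(les_med)
    les_med[fb] <- 0.5 * rd_med[fb]
    les_sd[is.na(les_sd) | les_sd <= 0] <-
      sqrt(pmax(les_med[is.na(les_sd) | les_sd <= 0], 1) / 2)
    lesser_c[idx] <- pmax(0, round(rnorm(length(idx),
                                         les_med[idx] * b_cancer[idx],
                                         les_sd[idx])))
    # admix pseudo-cancer and normal counts
    rd_t <- round(alpha * sites$rd_n + (1 - alpha) * rd_c)
    lesser_t <- round(alpha * sites$lesser_n + (1 - alpha) * lesser_c)
    lesser_t <- pmin(lesser_t, rd_t)
    # hom sites keep their near-zero lesser fraction
    hom <- sites$geno == "hom"
    lesser_t[hom] <- rbinom(sum(hom), rd_t[hom], 0.005)
  })
  laf_t <- ifelse(rd_t > 0, pmin(lesser_t, rd_t - lesser_t) / rd_t, 0)
  laf_n <- ifelse(sites$rd_n > 0, sites$lesser_n / sites$rd_n, 0)
  snps <- data.table::data.table(
    chrom = sites$chrom, pos = sites$pos, geno = sites$geno,
    rd_t = as.numeric(rd_t), rd_n = as.numeric(sites$rd_n),
    laf_t = laf_t, laf_n = pmin(laf_n, 1 - laf_n))
  list(snps = snps, truth = truth)
}

#' Thin read counts to a lower coverage
#'
#' Binomial thinning with probability `to_cov/from_cov`, emulating random
#' removal of reads; preserves the expected somatic ratio of every event.
#'
#' @param counts non-negative integer vector.
#' @param from_cov,to_cov original and target coverage.
#' @param seed integer seed.
#' @return Thinned counts.
#' @export
downsample <- function(counts, from_cov, to_cov, seed = 1L) {
  stopifnot(to_cov <= from_cov)
  if (to_cov == from_cov) return(counts)
  with_local_seed(seed, rbinom(length(counts), counts, to_cov / from_cov))
}

# thin the paired table (both libraries) to cfg$downsample_to
.downsample_snps <- function(snps, cfg) {
  if (cfg$downsample_to >= cfg$base_coverage) return(snps)
  p <- cfg$downsample_to / cfg$base_coverage
  with_local_seed(cfg$seed + 104729L, {
    for (side in c("t", "n")) {
      rd <- snps[[paste0("rd_", side)]]
      laf <- snps[[paste0("laf_", side)]]
      lesser <- round(laf * rd)
      l2 <- rbinom(length(rd), lesser, p)
      r2 <- l2 + rbinom(length(rd), rd - lesser, p)
      snps[[paste0("rd_", side)]] <- as.numeric(r2)
      snps[[paste0("laf_", side)]] <-
        ifelse(r2 > 0, pmin(l2, r2 - l2) / r2, 0)
    }
  })
  snps
}

#' Simulate one paired cancer genome
#'
#' Runs the full protocol: template, event placement, admixture mixing and
#' coverage thinning.
#'
#' @param cfg a [sim_config()].
#' @param events event table (see [place_events_and_mix()]).
#' @return list with `snps` (per-SNP table) and `truth` (event table).
#' @export
simulate_genome <- function(cfg, events) {
  template <- make_template_normal(cfg)
  out <- place_events_and_mix(template, events, cfg)
  out$snps <- .downsample_snps(out$snps, cfg)
  out
}

#' Score SCNA calls against simulation truth
#'
#' A called segment is a positive SCNA call iff its somatic ratio is below
#' `ratio_lo` or above `ratio_hi`; a positive call is a true positive iff
#' both of its breakpoints fall within `bp_tol` of a truth event's
#' breakpoints.  Subclonal recovery counts truth events with
#' `subclonal_fraction < 1` overlapped (call midpoint inside the event) by
#' a segment classified subclonal.
#'
#' @param calls segment table with `chrom`, `start`, `end`,
#'   `somatic_ratio`, optionally `classification`.
#' @param truth truth event table from the simulator.
#' @param ratio_lo,ratio_hi positive-call cutoffs (defaults 0.8, 1.2).
#' @param bp_tol breakpoint tolerance in bp (default 1e5).
#' @return list with `sensitivity`, `precision`, `n_true`, `n_pos`,
#'   `n_tp`, per-size-stratum sensitivity (`sensitivity_small` < 1 Mb,
#'   `sensitivity_large` >= 1 Mb), `segments_per_large_event`,
#'   `subclonal_recovered`, `subclonal_total`, `subclonal_fp`.
#' @export
score_calls <- function(calls, truth, ratio_lo = 0.8, ratio_hi = 1.2,
                        bp_tol = 1e5) {
  calls <- as.data.frame(calls)
  truth <- as.data.frame(truth)
  pos <- calls$somatic_ratio < ratio_lo | calls$somatic_ratio > ratio_hi
  match_mat <- function(ci, ti) {
    calls$chrom[ci] == truth$chrom[ti] &
      abs(calls$start[ci] - truth$start[ti]) <= bp_tol &
      abs(calls$end[ci] - truth$end[ti]) <= bp_tol
  }
  n_call <- nrow(calls); n_true <- nrow(truth)
  tp_call <- logical(n_call)
  hit_true <- logical(n_true)
  for (ci in which(pos)) {
    for (ti in seq_len(n_true)) {
      if (match_mat(ci, ti)) {
        tp_call[ci] <- TRUE
        hit_true[ti] <- TRUE
      }
    }
  }
  size <- truth$end - truth$start
  mid <- (calls$start + calls$end) / 2
  seg_per_event <- vapply(which(size >= 1e6), function(ti) {
    sum(calls$chrom == truth$chrom[ti] & mid > truth$start[ti] &
          mid <= truth$end[ti])
  }, numeric(1))
  sub_true <- which(!is.na(truth$subclonal_fraction) &
                      truth$subclonal_fraction < 1)
  sub_call <- if (!is.null(calls$classification))
    which(calls$classification == "subclonal") else integer(0)
  ovl <- function(ci, ti) {
    if (calls$chrom[ci] != truth$chrom[ti]) return(0)
    max(0, min(calls$end[ci], truth$end[ti]) -
          max(calls$start[ci], truth$start[ti]))
  }
  # a truth subclonal event is recovered when a subclonal-classified call
  # covers at least half of it; a subclonal call is a false positive when
  # less than half of it lies inside subclonal truth
  sub_rec <- vapply(sub_true, function(ti) {
    any(vapply(sub_call, ovl, numeric(1), ti = ti) >=
          0.5 * (truth$end[ti] - truth$start[ti]))
  }, logical(1))
  sub_fp <- if (length(sub_call)) {
    vapply(sub_call, function(ci) {
      cov <- sum(vapply(sub_true, function(ti) ovl(ci, ti), numeric(1)))
      cov < 0.5 * (calls$end[ci] - calls$start[ci])
    }, logical(1))
  } else logical(0)
  list(
    sensitivity = if (n_true) mean(hit_true) else NA_real_,
    precision = if (any(pos)) sum(tp_call) / sum(pos) else NA_real_,
    n_true = n_true, n_pos = sum(pos), n_tp = sum(tp_call),
    sensitivity_small = if (any(size < 1e6)) mean(hit_true[size < 1e6])
                        else NA_real_,
    sensitivity_large = if (any(size >= 1e6)) mean(hit_true[size >= 1e6])
                        else NA_real_,
    segments_per_large_event = if (length(seg_per_event))
      mean(seg_per_event) else NA_real_,
    subclonal_recovered = sum(sub_rec), subclonal_total = length(sub_true),
    subclonal_fp = sum(sub_fp))
}

#' Default event layouts for the evaluation grids
#'
#' `kind = "subclonal"` mirrors the subclonality study: clonal anchor
#' events of all four types on the first six chromosomes plus 4-5
#' one-copy subclonal events larger than 10 Mb (fractions 0.2/0.4) on
#' chromosomes 12-15.  `kind = "small"` plants sub-Mb clonal events
#' (10 kb-1 Mb) and one >= 1 Mb event per chromosome for the
#' segmentation-sensitivity study.
#'
#' @param kind `"subclonal"` or `"small"`.
#' @param replicate replicate index (varies the subclonal event count 4/5
#'   and sizes deterministically).
#' @return list with `chrom_lengths` and `events` ready for
#'   [simulate_genome()].
#' @export
sim_event_layout <- function(kind = c("subclonal", "small"),
                             replicate = 1L) {
  kind <- match.arg(kind)
  if (kind == "subclonal") {
    chrom_lengths <- setNames(c(rep(8e6, 6), rep(24e6, 4)),
                              c(paste0("chr", 1:6), paste0("chr", 12:15)))
    clonal_types <- c("double_deletion", "LOH", "gain1", "gain2")
    ev <- list()
    # two clonal events per small chromosome, types cycling, 0.4-2.5 Mb
    sizes <- c(4e5, 2.5e6, 8e5, 1.5e6, 2e6, 6e5, 1.2e6, 2.2e6, 5e5, 1.8e6,
               9e5, 2.4e6)
    k <- 0L
    for (i in 1:6) {
      for (j in 1:2) {
        k <- k + 1L
        start <- (j - 1) * 4e6 + 5e5 + ((replicate - 1) %% 3) * 2e5
        ev[[length(ev) + 1L]] <- data.frame(
          chrom = paste0("chr", i), start = start,
          end = start + sizes[k],
          type = clonal_types[(k - 1L) %% 4L + 1L],
          subclonal_fraction = 1)
      }
    }
    # subclonal one-copy events > 10 Mb on chr12-15; 5 on odd replicates,
    # 4 on even (paper plants 4-5 per genome)
    n_sub <- if (replicate %% 2L == 1L) 5L else 4L
    sub_types <- c("gain1", "LOH", "gain1", "LOH", "gain1")
    fracs <- c(0.2, 0.4, 0.4, 0.2, 0.4)
    ch_sub <- paste0("chr", c(12, 13, 14, 15, 12))
    starts <- c(5e5, 8e5, 6e5, 1e6, 12.5e6)
    lens <- c(10.5e6, 11e6, 12e6, 10.2e6, 11e6)
    for (s in seq_len(n_sub)) {
      ev[[length(ev) + 1L]] <- data.frame(
        chrom = ch_sub[s], start = starts[s], end = starts[s] + lens[s],
        type = sub_types[s], subclonal_fraction = fracs[s])
    }
    events <- do.call(rbind, ev)
  } else {
    chrom_lengths <- setNames(rep(1e7, 6), paste0("chr", 1:6))
    clonal_types <- c("LOH", "gain1", "double_deletion", "gain2")
    small_sizes <- c(1.2e4, 2.5e4, 6e4, 1.5e5, 4e5, 8e5)
    ev <- list()
    for (i in 1:6) {
      # four sub-Mb events + one large event per chromosome
      ssz <- small_sizes[((i - 1L + replicate + c(0L, 2L, 4L, 1L)) %% 6L) + 1L]
      starts <- c(4e5, 2e6, 4e6, 6e6)
      for (j in 1:4) {
        ev[[length(ev) + 1L]] <- data.frame(
          chrom = paste0("chr", i), start = starts[j],
          end = starts[j] + ssz[j],
          type = clonal_types[(i + j) %% 4L + 1L],
          subclonal_fraction = 1)
      }
      ev[[length(ev) + 1L]] <- data.frame(
        chrom = paste0("chr", i), start = 8e6,
        end = 8e6 + 1.5e6 + 2e5 * (i %% 3),
        type = clonal_types[i %% 4L + 1L], subclonal_fraction = 1)
    }
    events <- do.call(rbind, ev)
  }
  rownames(events) <- NULL
  list(chrom_lengths = chrom_lengths, events = events)
}
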