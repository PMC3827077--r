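#' @name cli_reporting
#' @title Pipeline orchestration and reporting
#' @description Runs the four analysis stages — segmentation, somatic-ratio
#'   estimation with refinement, admixture-rate estimation, subclonality
#'   characterization — and assembles the four outputs: the sample
#'   admixture rate, per-segment allelic copy numbers, per-SCNA subclonal
#'   fractions, and the aberration event list.  Every stage is also an
#'   exported function and can be called independently.
NULL

# build the per-chromosome segment table from the SNP table
.segment_all <- function(snps, cfg, seed) {
  lv <- chrom_levels(snps$chrom)
  out <- list()
  offset <- 0L
  for (ch in lv) {
    idx <- which(snps$chrom == ch)
    sub <- snps[idx, ]
    het <- which(sub$geno == "het")
    if (length(het) >= 2L) {
      segs <- segment_chromosome(sub$pos[het], sub$laf_t[het], cfg,
                                 seed = seed + match(ch, lv))
    } else {
      segs <- data.frame(start = sub$pos[1] - 1, end = sub$pos[nrow(sub)],
                         first_idx = 1L, last_idx = max(length(het), 1L),
                         n_het = length(het),
                         mean_laf = mean(sub$laf_t[het]))
    }
    # map segment bp ranges to row ranges over ALL SNPs of the chromosome
    segs$chrom <- ch
    segs$snp_first <- offset + findInterval(segs$start, sub$pos) + 1L
    segs$snp_last <- offset + findInterval(segs$end, sub$pos)
    segs$n_snps <- segs$snp_last - segs$snp_first + 1L
    out[[ch]] <- segs
    offset <- offset + nrow(sub)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("chrom", "start", "end", "snp_first", "snp_last", "n_snps",
          "n_het", "mean_laf", "first_idx", "last_idx")]
}

#' Run the full SCNA calling pipeline
#'
#' @param snps per-SNP table from [load_snp_table()] or the simulator.
#' @param cfg configuration from [scna_config()].
#' @param gc_correction apply GC correction when a `gc` column is present
#'   (default TRUE).
#' @return An object of class `"scna_result"`: a list with `alpha`,
#'   `alpha_adjusted` (FALSE when the 0.8 reporting cap was hit and
#'   downstream adjustment was skipped), `K`, `centers`, `segments`
#'   (per-segment table with ratios, copy states, posteriors, clonality,
#'   allelic copies, subclonality p-values and fractions) and `events`
#'   (rows of `segments` labeled gain/loss/LOH/cnLOH).
#' @export
run_pipeline <- function(snps, cfg = scna_config(), gc_correction = TRUE) {
  snps <- data.table::as.data.table(snps)
  lv <- chrom_levels(snps$chrom)
  snps <- snps[order(match(snps$chrom, lv), snps$pos), ]
  snps <- median_normalize(snps, "match_medians")
  if (gc_correction && !is.null(snps$gc))
    snps <- gc_correct(snps, degree = cfg$gc$degree,
                       min_fit = cfg$gc$min_fit,
                       spacing_bp = cfg$gc$spacing_bp)
  seed <- cfg$seed

  segments <- .segment_all(snps, cfg, seed)
  segments$somatic_ratio <- vapply(seq_len(nrow(segments)), function(k) {
    idx <- segments$snp_first[k]:segments$snp_last[k]
    estimate_somatic_ratio(snps$rd_t_use[idx], snps$rd_n[idx],
                           method = cfg$ratio$method, trim = cfg$ratio$trim,
                           grid = cfg$ratio$grid,
                           grid_step = cfg$ratio$grid_step)
  }, numeric(1))
  segments <- merge_refine(segments, snps, T = cfg$ratio$merge_T, cfg = cfg)
  segments$somatic_copy_level <- 2 * segments$somatic_ratio

  fit <- fit_admixture(segments, cfg, seed = seed)
  segments$copy_state <- fit$copy_state
  segments$posterior <- fit$posterior
  segments$clonality <- fit$clonality

  capped <- fit$alpha >= cfg$admixture$max_alpha
  if (capped) {
    warning("estimated admixture rate hits the ", cfg$admixture$max_alpha,
            " cap; reporting segmentation results without adjustment")
    res <- list(alpha = fit$alpha, alpha_adjusted = FALSE, K = fit$K,
                centers = fit$centers, segments = segments,
                events = segments[0, ], snps = snps)
    class(res) <- "scna_result"
    return(res)
  }
  segments <- characterize_subclonality(segments, snps, fit$alpha, cfg,
                                        seed = seed + 1000L)
  events <- segments[segments$event != "neutral", , drop = FALSE]
  res <- list(alpha = fit$alpha, alpha_adjusted = TRUE, K = fit$K,
              centers = fit$centers, segments = segments, events = events,
              snps = snps)
  class(res) <- "scna_result"
  res
}

#' @export
print.scna_result <- function(x, ...) {
  cat("SCNA calling result\n")
  cat(sprintf("  admixture rate: %.3f%s\n", x$alpha,
              if (!x$alpha_adjusted) " (cap hit; unadjusted output)" else ""))
  cat(sprintf("  mixture components: %d at levels %s\n", x$K,
              paste(sprintf("%.2f", x$centers), collapse = ", ")))
  cat(sprintf("  segments: %d on %d chromosome(s); aberration events: %d\n",
              nrow(x$segments), length(unique(x$segments$chrom)),
              nrow(x$events)))
  if (nrow(x$events)) {
    tab <- table(x$events$event)
    cat("  events by type:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    nsub <- sum(x$events$classification == "subclonal")
    cat(sprintf("  subclonal events: %d\n", nsub))
  }
  invisible(x)
}

#' Export pipeline outputs to disk
#'
#' Writes the segment table and event list as TSV and the sample summary
#' (alpha, component count, centers) as JSON.
#'
#' @param result an `"scna_result"`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seg_path <- file.path(dir, "segments.tsv")
  ev_path <- file.path(dir, "events.tsv")
  js_path <- file.path(dir, "sample.json")
  data.table::fwrite(result$segments, seg_path, sep = "\t")
  data.table::fwrite(result$events, ev_path, sep = "\t")
  jsonlite::write_json(
    list(alpha = result$alpha, alpha_adjusted = result$alpha_adjusted,
         K = result$K, centers = result$centers),
    js_path, auto_unbox = TRUE, digits = NA)
  invisible(c(seg_path, ev_path, js_path))
}

#' Run a simulation-evaluation grid
#'
#' For each (admixture rate, coverage) cell, simulates `replicates` paired
#' genomes with the requested event layout, runs the full pipeline and
#' scores the calls against truth.  This is the evaluation harness used by
#' the acceptance checks.
#'
#' @param alphas admixture rates to simulate.
#' @param coverages target coverages (template is 60x; lower values are
#'   reached by binomial thinning).  Recycled against `alphas` when
#'   `paired = TRUE`, crossed otherwise.
#' @param replicates genomes per cell.
#' @param kind event layout kind, see [sim_event_layout()].
#' @param seed integer base seed.
#' @param paired if TRUE, `alphas` and `coverages` are parallel vectors of
#'   cells; if FALSE the full grid is crossed.
#' @param cfg pipeline configuration.
#' @return data.frame with one row per simulated genome: cell parameters,
#'   estimated alpha and every [score_calls()] metric.
#' @export
scna_evaluate_grid <- function(alphas = c(0.2, 0.4), coverages = 60,
                               replicates = 1L, kind = "subclonal",
                               seed = 1L, paired = FALSE,
                               cfg = scna_config()) {
  cells <- if (paired) data.frame(alpha = alphas, coverage = coverages)
    else expand.grid(alpha = alphas, coverage = coverages)
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    for (rep_i in seq_len(replicates)) {
      lay <- sim_event_layout(kind, replicate = rep_i)
      gseed <- (seed * 1000L + ci * 100L + rep_i) %% .Machine$integer.max
      scfg <- sim_config(chrom_lengths = lay$chrom_lengths,
                         admixture_rate = cells$alpha[ci],
                         downsample_to = cells$coverage[ci],
                         seed = gseed)
      sim <- simulate_genome(scfg, lay$events)
      pcfg <- cfg
      pcfg$seed <- gseed + 1L
      res <- run_pipeline(sim$snps, pcfg)
      sc <- score_calls(res$segments, sim$truth)
      rows[[length(rows) + 1L]] <- data.frame(
        alpha = cells$alpha[ci], coverage = cells$coverage[ci],
        replicate = rep_i, alpha_hat = res$alpha,
        sensitivity = sc$sensitivity, precision = sc$precision,
        sensitivity_small = sc$sensitivity_small,
        sensitivity_large = sc$sensitivity_large,
        segments_per_large_event = sc$segments_per_large_event,
        subclonal_recovered = sc$subclonal_recovered,
        subclonal_total = sc$subclonal_total,
        subclonal_fp = sc$subclonal_fp)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
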