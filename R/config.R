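#' Pipeline configuration
#'
#' Builds the nested configuration list consumed by [run_pipeline()] and the
#' individual stage functions.  Any subset of the defaults can be overridden
#' by passing named lists, e.g. `scna_config(smoothing = list(t = 3))`.
#'
#' Sections and defaults:
#' \describe{
#'   \item{smoothing}{`half_width = 5` flanking points per side,
#'     `t = 2` outlier threshold in SD units.}
#'   \item{segmentation}{`alpha = 0.01` significance for a split,
#'     `nperm = 1000` permutations, `pad_n = 100` pseudo points per end,
#'     `bic_variant = "cumseg"` (inflated penalty
#'     `k log(n) log(log n)`; `"classic"` gives plain `k log n`),
#'     `perm_nmax = 1000` longest sequence tested by permutation
#'     (longer sequences use a seeded Monte-Carlo null quantile),
#'     `wmax = 256` exact short-arc width, `grid_target = 512` coarse-grid
#'     resolution, `min_width = 3` minimum arc width in points,
#'     `min_het = 10` minimum heterozygous sites per chromosome.}
#'   \item{ratio}{`method = "gh_mle"`, `trim = c(5, 95)` percentile trim of
#'     per-SNP ratios, `merge_T = 0.05` adjacent-segment merge tolerance,
#'     `grid = c(0.01, 8)` search range, `grid_step = 0.01` coarse step before
#'     golden-section refinement.}
#'   \item{admixture}{`iters = 10000`, `burn_in = 2000`, `hyper_var = 0.01`
#'     component variance, `min_center_gap = 0.2`, `k_min = 3`, `k_max = 8`,
#'     `dirichlet = 1` prior concentration, `max_alpha = 0.8` reporting cap,
#'     `posterior_threshold = 0.9` candidate-subclonal cutoff.}
#'   \item{subclonality}{`neutral_band = 0.05` half-width of the copy-neutral
#'     guard band on the adjusted ratio, `p_cutoff = 0.05`,
#'     `n_boot = 200` bootstrap resamples for the null SD,
#'     `boot_max_snps = 800` resample-size cap (SD rescaled by sqrt(m/n)),
#'     `min_sigma = 1e-4` floor on the null SD.}
#' }
#'
#' @param ... named lists overriding individual sections (see Details).
#' @param seed integer seed driving every stochastic stage.
#' @return A named list of sections with class `"scna_config"`.
#' @examples
#' cfg <- scna_config(ratio = list(merge_T = 0.1), seed = 7)
#' cfg$ratio$merge_T
#' @export
scna_config <- function(..., seed = 1L) {
  cfg <- list(
    smoothing = list(half_width = 5L, t = 2),
    segmentation = list(alpha = 0.01, nperm = 1000L, pad_n = 100L,
                        bic_variant = "cumseg", perm_nmax = 1000L,
                        wmax = 256L, grid_target = 512L, min_width = 3L,
                        min_het = 10L),
    ratio = list(method = "gh_mle", trim = c(5, 95), merge_T = 0.05,
                 grid = c(0.01, 8), grid_step = 0.01),
    admixture = list(iters = 10000L, burn_in = 2000L, hyper_var = 0.01,
                     min_center_gap = 0.2, k_min = 3L, k_max = 8L,
                     dirichlet = 1, max_alpha = 0.8,
                     posterior_threshold = 0.9),
    subclonality = list(neutral_band = 0.05, p_cutoff = 0.05, n_boot = 200L,
                        boot_max_snps = 800L, min_sigma = 1e-4),
    gc = list(degree = 2L, min_fit = 30L, spacing_bp = 1e6),
    seed = as.integer(seed)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config section: ", nm)
    if (is.list(cfg[[nm]])) {
      bad <- setdiff(names(over[[nm]]), names(cfg[[nm]]))
      if (length(bad)) stop("unknown config key: ", nm, "$", bad[1])
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  structure(cfg, class = "scna_config")
}
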