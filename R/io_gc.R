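#' @name io_gc
#' @title Paired-SNP input, library normalization and GC-bias correction
#' @description Functions that read the per-SNP tumor/normal table, compute
#'   read-count ratios against the library medians, and regress out the
#'   GC-content bias in read depth.
NULL

.required_cols <- c("chrom", "pos", "geno", "rd_t", "rd_n", "laf_t", "laf_n")

# order chromosomes naturally: numeric labels first (1 < 2 < ... < 22),
# then the rest (X, Y, ...) alphabetically
chrom_levels <- function(chrom) {
  u <- unique(as.character(chrom))
  num <- suppressWarnings(as.numeric(sub("^chr", "", u)))
  c(u[!is.na(num)][order(num[!is.na(num)])], sort(u[is.na(num)]))
}

validate_snp_records <- function(df) {
  miss <- setdiff(.required_cols, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$pos) | !is.finite(df$rd_t) | !is.finite(df$rd_n) |
                 !is.finite(df$laf_t) | !is.finite(df$laf_n))
  if (length(bad)) stop("malformed row at line ", bad[1] + 1L,
                        ": non-numeric or missing value")
  if (any(df$laf_t < 0 | df$laf_t > 0.5 | df$laf_n < 0 | df$laf_n > 0.5))
    stop("LAF values must lie in [0, 0.5] (mirror BAF at 0.5 first)")
  if (any(df$rd_t < 0 | df$rd_n < 0)) stop("read depths must be non-negative")
  if (!all(df$geno %in% c("het", "hom")))
    stop("geno must be 'het' or 'hom'")
  invisible(df)
}

#' Mirror a B-allele frequency into a lesser-allele frequency
#'
#' @param baf numeric vector of B-allele frequencies in \[0, 1\].
#' @return `min(baf, 1 - baf)`, the lesser-allele frequency in \[0, 0.5\].
#' @examples
#' laf_from_baf(c(0.7, 0.5, 0.1))
#' @export
laf_from_baf <- function(baf) pmin(baf, 1 - baf)

#' Load a paired tumor/normal per-SNP table
#'
#' Reads either a tab-delimited table with columns
#' `chrom, pos, geno, rd_t, rd_n, laf_t, laf_n` (optional `gc`, `qual`) or a
#' pair of VCF files (tumor + normal) matched on chrom/pos, with depth taken
#' from the per-sample `DP` field and LAF computed from allelic depths `AD`.
#' Sites with quality score below `min_qual` are dropped; unsorted input is
#' sorted with a message.
#'
#' @param path path to the TSV file (ignored for `format = "vcf-pair"`).
#' @param format `"tsv"` or `"vcf-pair"`.
#' @param tumor_vcf,normal_vcf VCF paths for `format = "vcf-pair"`.
#' @param min_qual quality-score filter threshold (default 10).
#' @return A `data.table` of SNP records sorted by (chrom, pos), one row per
#'   paired site, LAF mirrored at 0.5 and genotype classified from the
#'   normal sample.
#' @export
load_snp_table <- function(path, format = c("tsv", "vcf-pair"),
                           tumor_vcf = NULL, normal_vcf = NULL,
                           min_qual = 10) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- data.table::fread(path, header = TRUE, sep = "\t",
                            colClasses = list(character = "chrom"))
    validate_snp_records(df)
    if ("qual" %in% names(df)) {
      df <- df[df$qual >= min_qual, ]
    }
  } else {
    df <- read_vcf_pair(tumor_vcf, normal_vcf, min_qual = min_qual)
  }
  df <- data.table::as.data.table(df)
  lv <- chrom_levels(df$chrom)
  ord <- order(match(df$chrom, lv), df$pos)
  if (is.unsorted(ord)) {
    message("input not sorted by (chrom, pos); sorting")
    df <- df[ord, ]
  }
  df$laf_t <- pmin(df$laf_t, 1 - df$laf_t)
  df$laf_n <- pmin(df$laf_n, 1 - df$laf_n)
  df[]
}

# Pair two single-sample VCFs on chrom+pos.  Depth from geno DP, allelic
# depths from AD; genotype class from the normal GT.
read_vcf_pair <- function(tumor_vcf, normal_vcf, min_qual = 10) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VariantAnnotation is required for vcf-pair input")
  read_one <- function(f) {
    v <- VariantAnnotation::readVcf(f)
    gr <- SummarizedExperiment::rowRanges(v)
    ad <- VariantAnnotation::geno(v)$AD
    baf <- vapply(seq_len(nrow(v)), function(i) {
      a <- unlist(ad[i, 1])
      if (length(a) < 2 || sum(a) == 0) return(NA_real_)
      a[2] / sum(a)
    }, numeric(1))
    data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      pos = GenomicRanges::start(gr),
      qual = as.numeric(gr$QUAL),
      gt = as.character(VariantAnnotation::geno(v)$GT[, 1]),
      dp = as.numeric(VariantAnnotation::geno(v)$DP[, 1]),
      baf = baf)
  }
  tu <- read_one(tumor_vcf)
  no <- read_one(normal_vcf)
  m <- merge(no, tu, by = c("chrom", "pos"), suffixes = c("_n", "_t"))
  m <- m[!is.na(m$baf_n) & !is.na(m$baf_t) &
           m$qual_n >= min_qual & m$qual_t >= min_qual, ]
  data.table::data.table(
    chrom = m$chrom, pos = m$pos,
    geno = ifelse(m$gt_n %in% c("0/1", "0|1", "1/0", "1|0"), "het", "hom"),
    rd_t = m$dp_t, rd_n = m$dp_n,
    laf_t = laf_from_baf(m$baf_t), laf_n = laf_from_baf(m$baf_n))
}

#' Normalize read depths against the library medians
#'
#' Adds read-count ratio columns `ratio_t = rd_t / median(rd_t)` and
#' `ratio_n = rd_n / median(rd_n)`, plus `rd_t_use`: the tumor depths,
#' rescaled in `match_medians` mode so that the tumor library median equals
#' the normal library median (used downstream by the somatic-ratio MLE).
#'
#' @param records SNP record table (see [load_snp_table()]).
#' @param mode `"match_medians"` (default) or `"none"`.
#' @return The table with `ratio_t`, `ratio_n`, `rd_t_use` columns added.
#' @export
median_normalize <- function(records, mode = c("match_medians", "none")) {
  mode <- match.arg(mode)
  records <- data.table::as.data.table(records)
  med_t <- median(records$rd_t)
  med_n <- median(records$rd_n)
  if (med_t == 0 || med_n == 0) stop("library median depth is zero")
  records$ratio_t <- records$rd_t / med_t
  records$ratio_n <- records$rd_n / med_n
  records$rd_t_use <- if (mode == "match_medians")
    records$rd_t * med_n / med_t else records$rd_t
  records[]
}

# Greedy left-to-right thinning: keep a SNP only if it is at least gap_bp
# from the previously kept one on the same chromosome.
.spaced_subset <- function(chrom, pos, gap_bp) {
  keep <- logical(length(pos))
  last <- -Inf; last_chr <- ""
  for (i in seq_along(pos)) {
    if (chrom[i] != last_chr || pos[i] - last >= gap_bp) {
      keep[i] <- TRUE
      last <- pos[i]; last_chr <- chrom[i]
    }
  }
  keep
}

.autosome <- function(chrom) {
  !toupper(sub("^chr", "", chrom)) %in% c("X", "Y", "M", "MT")
}

#' Correct GC-content bias in read-count ratios
#'
#' Fits a polynomial regression (default quadratic) of the read-count ratio
#' on local GC fraction and replaces each ratio by its residual plus 1, so
#' that copy-neutral segments stay centered at ratio 1.  The regression is
#' fitted only on a confounder-free subset of SNPs: autosomes, pairwise at
#' least 1 Mb apart (greedy left-to-right), LAF above 0.4 and read-count
#' ratio inside (0.8, 1.25) in both samples; the correction is applied to
#' every record.  With fewer than `min_fit` qualifying SNPs the correction
#' is skipped with a warning.
#'
#' @param records output of [median_normalize()] with a `gc` column in
#'   \[0, 1\].
#' @param degree polynomial degree of the regression (default 2).
#' @param min_fit minimum fitting-subset size (default 30).
#' @param spacing_bp minimum spacing of fitting SNPs (default 1e6).
#' @return The table with `ratio_t` and `ratio_n` replaced by GC-corrected
#'   values.
#' @export
gc_correct <- function(records, degree = 2L, min_fit = 30L,
                       spacing_bp = 1e6) {
  records <- data.table::as.data.table(records)
  if (is.null(records$gc)) stop("no 'gc' column; cannot correct GC bias")
  if (is.null(records$ratio_t)) stop("run median_normalize() first")
  fit_set <- .autosome(records$chrom) &
    records$laf_t > 0.4 & records$laf_n > 0.4 &
    records$ratio_t > 0.8 & records$ratio_t < 1.25 &
    records$ratio_n > 0.8 & records$ratio_n < 1.25
  fit_set[fit_set] <- .spaced_subset(records$chrom[fit_set],
                                     records$pos[fit_set], spacing_bp)
  if (sum(fit_set) < min_fit) {
    warning("only ", sum(fit_set), " SNPs pass GC-fit filters (< ", min_fit,
            "); skipping GC correction")
    return(records[])
  }
  for (col in c("ratio_t", "ratio_n")) {
    dat <- data.frame(y = records[[col]][fit_set], gc = records$gc[fit_set])
    if (stats::sd(dat$gc) == 0) {
      # degenerate regressor: correction is a constant recentering
      records[[col]] <- records[[col]] - mean(dat$y) + 1
      next
    }
    fm <- lm(y ~ poly(gc, degree, raw = TRUE), data = dat)
    pred <- stats::predict(fm, newdata = data.frame(gc = records$gc))
    records[[col]] <- records[[col]] - pred + 1
  }
  records[]
}
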