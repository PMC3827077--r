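#' Outlier smoothing of a LAF sequence
#'
#' Median-replacement smoothing applied to the lesser-allele-frequency
#' sequence before segmentation.  For each index `i`, the smoothing region
#' is `[i - half_width, i + half_width]` (truncated at the sequence
#' boundaries).  If the point deviates from the region mean by more than
#' `t` sample standard deviations it is replaced by the region median;
#' otherwise it is left bitwise unchanged.  Region statistics are always
#' computed on the original values, so the result does not depend on
#' processing order.
#'
#' @param x numeric vector of LAF values in \[0, 0.5\].
#' @param half_width number of flanking points per side (default 5).
#' @param t outlier threshold in SD units (default 2).
#' @return Smoothed vector, same length as `x`.
#' @examples
#' x <- c(rep(0.5, 6), 0, rep(0.5, 6))
#' smooth_laf(x, half_width = 3)
#' @export
smooth_laf <- function(x, half_width = 5L, t = 2) {
  stopifnot(half_width >= 1, t > 0)
  n <- length(x)
  if (n < 2L * half_width + 1L) {
    warning("sequence shorter than smoothing window; returned unchanged")
    return(x)
  }
  out <- x
  for (i in seq_len(n)) {
    lo <- max(1L, i - half_width)
    hi <- min(n, i + half_width)
    region <- x[lo:hi]
    s <- sd(region)
    if (is.na(s) || s == 0) next
    if (abs(x[i] - mean(region)) > t * s) out[i] <- median(region)
  }
  out
}
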