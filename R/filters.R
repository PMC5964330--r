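#' Minimum-count window filter
#'
#' Keeps a window when its summed count over all samples of the contrast (ChIP
#' and input together) is at least \code{min_total}.
#'
#' @param counts Window x sample count matrix.
#' @param min_total Minimum row sum (default 20).
#' @return Logical vector, one entry per window.
#' @export
filter_min_count <- function(counts, min_total = 20) {
  counts <- as.matrix(counts)
  rowSums(counts) >= min_total
}

#' Global-background window filter
#'
#' The genome is tiled into disjoint bins (default 10 kb); the background rate
#' is the median bin count rescaled to per-bp units. A window is kept when its
#' per-bp ChIP rate exceeds the background rate by strictly more than
#' \code{min_log2fc} in log2 units. A pseudo-count is added to both counts
#' before forming rates, so all-zero windows are handled.
#'
#' @param window_counts Summed ChIP counts per window (vector).
#' @param window_width Window width(s) in bp (scalar or vector).
#' @param bin_counts Summed ChIP counts in the disjoint background bins.
#' @param bin_size Background bin size in bp (default 10000).
#' @param min_log2fc Strict log2 fold-change cutoff (default 2).
#' @param pseudo_count Added to both counts (default 0.5).
#' @return Logical vector, one entry per window.
#' @export
filter_global_background <- function(window_counts, window_width, bin_counts,
                                     bin_size = 10000, min_log2fc = 2,
                                     pseudo_count = 0.5) {
  if (!length(bin_counts) || all(bin_counts == 0))
    stop("degenerate background: all background bins have zero counts")
  bg_rate <- (median(bin_counts) + pseudo_count) / bin_size
  w_rate <- (window_counts + pseudo_count) / window_width
  log2(w_rate / bg_rate) > min_log2fc
}

#' Trimmed mean of M-values normalization factors
#'
#' Computes per-sample TMM scaling factors on binned counts: per-bin log
#' ratios (M) and average log abundances (A) against a reference sample are
#' doubly trimmed (30 percent of M, 5 percent of A by default) and the factor
#' is 2 to the untrimmed-weight mean of the surviving M values. Bins with a
#' zero in any sample are excluded. Factors are rescaled so their geometric
#' mean is 1; they multiply the library sizes.
#'
#' @param binned_counts Bin x sample count matrix (>= 2 samples).
#' @param lib_sizes Library sizes; default column sums.
#' @param logratio_trim Fraction of M values trimmed at each tail via the
#'   two-sided rule (default 0.3).
#' @param abs_trim Fraction of A values trimmed (default 0.05).
#' @return Named numeric vector of factors, geometric mean 1.
#' @export
tmm_factors <- function(binned_counts, lib_sizes = colSums(binned_counts),
                        logratio_trim = 0.3, abs_trim = 0.05) {
  x <- as.matrix(binned_counts)
  ns <- ncol(x)
  if (ns < 2) {
    warning("single sample: TMM factor fixed at 1")
    return(setNames(rep(1, ns), colnames(x)))
  }
  rates <- sweep(x, 2, lib_sizes, "/")
  # reference: sample whose 75th percentile rate is closest to the mean
  uq <- apply(rates, 2, quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ns), function(s) {
    if (s == ref) return(1)
    keep <- x[, s] > 0 & x[, ref] > 0
    if (!any(keep)) return(1)
    m <- log2(rates[keep, s] / rates[keep, ref])
    a <- 0.5 * log2(rates[keep, s] * rates[keep, ref])
    n <- length(m)
    lo_m <- floor(n * logratio_trim) + 1
    hi_m <- n + 1 - lo_m
    lo_a <- floor(n * abs_trim) + 1
    hi_a <- n + 1 - lo_a
    rm_ <- rank(m)
    ra <- rank(a)
    kept <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
    if (!any(kept)) return(1)
    2 ^ mean(m[kept])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(x))
}
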