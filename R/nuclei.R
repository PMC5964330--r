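#' Single-nucleus QC by median absolute deviation
#'
#' A nucleus fails when either metric (log library size, log number of
#' expressed genes) lies strictly more than k MADs below that metric's median;
#' only the low tail is penalized. The MAD uses the 1.4826 consistency
#' constant. If a metric has MAD 0, no nucleus fails on it (with a warning).
#'
#' @param metrics data.frame with columns \code{nucleus_id},
#'   \code{log_libsize}, \code{log_genes} (extra metric columns starting with
#'   "log_" are checked too).
#' @param k Number of MADs (default 3).
#' @return The input with a logical \code{pass} column appended.
#' @export
mad_qc_filter <- function(metrics, k = 3) {
  stopifnot(k > 0, nrow(metrics) >= 3)
  metric_cols <- grep("^log_", names(metrics), value = TRUE)
  if (!length(metric_cols)) stop("no log_ metric columns found")
  fail <- rep(FALSE, nrow(metrics))
  for (col in metric_cols) {
    x <- metrics[[col]]
    m <- mad(x)  # 1.4826 * median(|x - median(x)|)
    if (m == 0) {
      warning("MAD of ", col, " is 0; no nucleus fails on this metric")
      next
    }
    fail <- fail | (x < median(x) - k * m)
  }
  metrics$pass <- !fail
  metrics
}

#' Mean-variance decomposition of expression variance
#'
#' Fits a loess trend of per-gene total variance against mean log-expression;
#' the fitted value is the technical component and the biological component is
#' the excess over the trend. A gene is a highly variable gene (HVG) when its
#' biological component significantly exceeds \code{bio_threshold}: the total
#' variance is compared to (technical + bio_threshold) with a scaled
#' chi-square test on n - 1 degrees of freedom, BH-corrected.
#'
#' @param means Per-gene mean log-expression.
#' @param variances Per-gene total variance of log-expression.
#' @param n_obs Number of cells the variances were computed from.
#' @param span Loess span (default 0.3; small spans need many genes).
#' @param bio_threshold Biological-variance floor tested against (default 0.5).
#' @param fdr HVG significance cutoff on BH-adjusted p (default 0.05).
#' @return data.frame mean, total, technical, biological, p, fdr, hvg.
#' @export
hvg_decompose <- function(means, variances, n_obs, span = 0.3,
                          bio_threshold = 0.5, fdr = 0.05) {
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (length(means) < 50) stop("need >= 50 genes to fit the trend")
  stopifnot(length(means) == length(variances), n_obs >= 2)
  fit <- loess(variances ~ means, span = span, degree = 2,
               family = "symmetric")
  technical <- pmax(0, predict(fit, means))
  biological <- variances - technical
  df <- n_obs - 1
  null_var <- technical + bio_threshold
  p <- pchisq(df * variances / null_var, df = df, lower.tail = FALSE)
  adj <- bh_adjust(p)
  data.frame(mean = means, total = variances, technical = technical,
             biological = biological, p = p, fdr = adj,
             hvg = adj <= fdr)
}

#' Spearman correlations between highly variable genes
#'
#' For every HVG pair, Spearman's rho and a permutation p-value: one gene's
#' values are shuffled \code{n_permutations} times and
#' p = (1 + #(|rho*| >= |rho|)) / (1 + n_permutations). Constant genes are
#' skipped with a flag.
#'
#' @param log_expr Gene x cell matrix of log-expression, rows named.
#' @param hvg_set Gene ids to correlate (>= 2).
#' @param n_permutations Number of permutations (>= 100).
#' @param seed Integer seed; identical seeds give identical p-values.
#' @return data.frame gene1, gene2, rho, p, skipped.
#' @export
hvg_correlations <- function(log_expr, hvg_set, n_permutations = 1000,
                             seed = 1L) {
  stopifnot(n_permutations >= 100, ncol(log_expr) >= 10)
  hvg_set <- intersect(hvg_set, rownames(log_expr))
  if (length(hvg_set) < 2) stop("need at least two HVGs present in the matrix")
  set.seed(as.integer(seed))
  pairs <- combn(hvg_set, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    x <- log_expr[g1, ]; y <- log_expr[g2, ]
    if (sd(x) == 0 || sd(y) == 0)
      return(data.frame(gene1 = g1, gene2 = g2, rho = NA_real_, p = NA_real_,
                        skipped = TRUE))
    rho <- cor(x, y, method = "spearman")
    perm <- vapply(seq_len(n_permutations), function(i)
      abs(cor(x, sample(y), method = "spearman")), numeric(1))
    p <- (1 + sum(perm >= abs(rho))) / (1 + n_permutations)
    data.frame(gene1 = g1, gene2 = g2, rho = rho, p = p, skipped = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
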