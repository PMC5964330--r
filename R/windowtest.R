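#' Per-window differential binding test (ChIP vs input)
#'
#' Fits a negative-binomial generalized linear model per window with a single
#' group term (ChIP vs input) and log effective library sizes (library size
#' times normalization factor) as offsets. With residual degrees of freedom,
#' dispersions are estimated with empirical-Bayes shrinkage toward a mean
#' trend and the test is the quasi-likelihood F-test. When either group has a
#' single sample and no residual degrees of freedom remain, the model is fit
#' at a fixed dispersion (default 0.05) and a likelihood-ratio chi-square test
#' is used instead; those rows are flagged.
#'
#' @param chip_counts Window x sample count matrix for the ChIP samples.
#' @param input_counts Window x sample count matrix for the input samples.
#' @param lib_sizes Library sizes for \code{cbind(chip, input)} columns;
#'   default column sums.
#' @param norm_factors TMM factors for the same columns (default 1).
#' @param fixed_dispersion NB dispersion for the no-replicate fallback.
#' @return data.frame with one row per window: \code{logFC} (ChIP over
#'   input, log2), \code{p}, and \code{method} ("ql_ftest" or
#'   "lrt_fixed_disp"). All-zero windows get p = 1 and logFC = 0.
#' @export
test_windows <- function(chip_counts, input_counts,
                         lib_sizes = NULL, norm_factors = NULL,
                         fixed_dispersion = 0.05) {
  chip_counts <- as.matrix(chip_counts)
  input_counts <- as.matrix(input_counts)
  stopifnot(nrow(chip_counts) == nrow(input_counts))
  y <- cbind(chip_counts, input_counts)
  n_chip <- ncol(chip_counts)
  n_input <- ncol(input_counts)
  group <- factor(rep(c("chip", "input"), c(n_chip, n_input)),
                  levels = c("input", "chip"))
  if (is.null(lib_sizes)) lib_sizes <- colSums(y)
  if (is.null(norm_factors)) norm_factors <- rep(1, ncol(y))
  design <- stats::model.matrix(~group)
  nonzero <- rowSums(y) > 0
  out <- data.frame(logFC = rep(0, nrow(y)), p = rep(1, nrow(y)),
                    method = rep(NA_character_, nrow(y)),
                    stringsAsFactors = FALSE)
  if (any(nonzero)) {
    dge <- edgeR::DGEList(counts = y[nonzero, , drop = FALSE],
                          lib.size = lib_sizes, norm.factors = norm_factors,
                          group = group)
    replicated <- (n_chip + n_input) > 2
    if (replicated) {
      dge <- edgeR::estimateDisp(dge, design)
      fit <- edgeR::glmQLFit(dge, design)
      res <- edgeR::glmQLFTest(fit, coef = 2)
      method <- "ql_ftest"
    } else {
      fit <- edgeR::glmFit(dge, design, dispersion = fixed_dispersion)
      res <- edgeR::glmLRT(fit, coef = 2)
      method <- "lrt_fixed_disp"
    }
    out$logFC[nonzero] <- res$table$logFC
    out$p[nonzero] <- res$table$PValue
    out$method[nonzero] <- method
  }
  if (!is.null(rownames(y))) rownames(out) <- rownames(y)
  out
}

#' Simes combined p-value
#'
#' For m component p-values, the Simes combination is
#' min over i of m * p_(i) / i, where p_(i) are the sorted values. It equals
#' the single p-value when m = 1 and never falls below min(p).
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return The combined p-value.
#' @examples
#' simes_pvalue(c(0.01, 0.04, 0.9))  # 0.03
#' @export
simes_pvalue <- function(p) {
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  if (any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  m <- length(p)
  min(m * sort(p) / seq_len(m))
}

#' Combine window p-values into per-region results
#'
#' Each gene's region-level p-value is the Simes combination over the
#' surviving windows mapped to it. Genes whose windows were all filtered out
#' are reported with \code{tested = FALSE} (treated as unmarked downstream),
#' never dropped from the universe.
#'
#' @param window_results data.frame from \code{\link{test_windows}}, rows
#'   aligned with \code{window_ids}.
#' @param window_ids Window ids of the tested (surviving) windows.
#' @param grid The \code{window_grid} mapping window_id to gene_id.
#' @param universe Optional gene ids guaranteed to appear in the output.
#' @return data.frame of class \code{region_results}: gene_id, p, n_windows,
#'   max_logfc, tested, method.
#' @export
combine_region_pvalues <- function(window_results, window_ids, grid,
                                   universe = unique(grid$gene_id)) {
  stopifnot(nrow(window_results) == length(window_ids))
  map <- grid[grid$window_id %in% window_ids, c("window_id", "gene_id")]
  idx <- match(map$window_id, window_ids)
  map$p <- window_results$p[idx]
  map$logFC <- window_results$logFC[idx]
  map$method <- window_results$method[idx]
  by_gene <- split(map, map$gene_id)
  res <- data.frame(gene_id = universe, p = NA_real_, n_windows = 0L,
                    max_logfc = NA_real_, tested = FALSE,
                    method = NA_character_, stringsAsFactors = FALSE)
  rownames(res) <- res$gene_id
  for (g in names(by_gene)) {
    if (!g %in% universe) next
    d <- by_gene[[g]]
    res[g, "p"] <- simes_pvalue(d$p)
    res[g, "n_windows"] <- nrow(d)
    res[g, "max_logfc"] <- d$logFC[which.max(abs(d$logFC))]
    res[g, "tested"] <- TRUE
    res[g, "method"] <- d$method[1]
  }
  rownames(res) <- NULL
  class(res) <- c("region_results", "data.frame")
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1. Input outside [0, 1]
#' is an error.
#'
#' @param p Numeric vector of p-values (NA allowed).
#' @return Adjusted values of the same length.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}
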