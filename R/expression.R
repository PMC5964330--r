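#' RPKM from raw counts
#'
#' RPKM = count * 1e9 / (gene length * library size): reads per kilobase of
#' gene model per million mapped reads.
#'
#' @param counts Gene x sample count matrix (or vector).
#' @param lengths Gene lengths in bp (> 0).
#' @param lib_sizes Per-sample library sizes (> 0); default column sums.
#' @return Matrix of RPKM values with the dimensions of \code{counts}.
#' @export
compute_rpkm <- function(counts, lengths,
                         lib_sizes = colSums(as.matrix(counts))) {
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  sweep(counts / lengths, 2, lib_sizes, "/") * 1e9
}

#' Silent-gene classification
#'
#' A gene is silent when log2(mean RPKM + 1) is strictly below the threshold;
#' at the default threshold of 1 this is exactly mean RPKM < 1.
#'
#' @param mean_rpkm Per-gene mean RPKM (per cell type).
#' @param threshold Cutoff on the log2(RPKM + 1) scale (default 1).
#' @return Logical vector.
#' @export
classify_silent <- function(mean_rpkm, threshold = 1) {
  log2(mean_rpkm + 1) < threshold
}

#' Expression by chromatin state
#'
#' For each state: box statistics of the members' log2(RPKM + 1) values and a
#' two-sided Wilcoxon rank-sum test of members against all non-member genes.
#' States with fewer than 2 members get statistics but no p-value.
#'
#' @param log_expr Named numeric vector of per-gene log2(RPKM + 1).
#' @param states A \code{state_assignment} covering the names of
#'   \code{log_expr}.
#' @return data.frame per state: n, median, q25, q75, whisker_lo, whisker_hi,
#'   p.
#' @export
state_expression_test <- function(log_expr, states) {
  stopifnot(!is.null(names(log_expr)))
  st <- setNames(as.character(states$state), states$gene_id)[names(log_expr)]
  rows <- lapply(chromatin_states(), function(s) {
    x <- log_expr[!is.na(st) & st == s]
    y <- log_expr[is.na(st) | st != s]
    n <- length(x)
    if (n == 0)
      return(data.frame(state = s, n = 0L, median = NA_real_, q25 = NA_real_,
                        q75 = NA_real_, whisker_lo = NA_real_,
                        whisker_hi = NA_real_, p = NA_real_))
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    wl <- min(x[x >= q[1] - 1.5 * iqr])
    wh <- max(x[x <= q[3] + 1.5 * iqr])
    p <- if (n >= 2 && length(y) >= 1)
      wilcox.test(x, y, alternative = "two.sided")$p.value else NA_real_
    data.frame(state = s, n = n, median = q[2], q25 = q[1], q75 = q[3],
               whisker_lo = wl, whisker_hi = wh, p = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regulated-gene selection from ribosome-capture contrasts
#'
#' Combines three inputs from a TRAP-style experiment: genes differentially
#' expressed in the captured (TRAP) fraction, genes differentially expressed
#' in the unbound (UB) fraction, and genes enriched in TRAP over UB. Under the
#' default rule, regulated genes are the TRAP-DE genes minus the UB-DE genes,
#' gated to TRAP-enriched genes:
#' up = (trap_de_up \\ ub_de) intersect trap_enriched (and symmetrically for
#' down). The alternative rule \code{"subtract_filtered"} instead subtracts
#' only those UB-DE genes that are not TRAP-enriched:
#' up = trap_de_up \\ (ub_de \\ trap_enriched).
#'
#' @param trap_de_up,trap_de_down Disjoint gene-id sets.
#' @param ub_de Gene ids differentially expressed in the unbound fraction.
#' @param trap_enriched Gene ids enriched in the captured fraction.
#' @param rule "gate_final" (default) or "subtract_filtered".
#' @return list(up, down, rule).
#' @export
select_stress_regulated <- function(trap_de_up, trap_de_down, ub_de,
                                    trap_enriched,
                                    rule = c("gate_final", "subtract_filtered")) {
  rule <- match.arg(rule)
  if (length(intersect(trap_de_up, trap_de_down)))
    stop("up and down input sets overlap")
  pick <- function(de) {
    if (rule == "gate_final") intersect(setdiff(de, ub_de), trap_enriched)
    else setdiff(de, setdiff(ub_de, trap_enriched))
  }
  list(up = sort(pick(trap_de_up)), down = sort(pick(trap_de_down)),
       rule = rule)
}
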