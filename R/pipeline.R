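#' Region-level mark calling for one histone modification
#'
#' Runs the full window engine for one mark and one cell type: minimum-count
#' and global-background window filters, TMM normalization on binned counts,
#' the per-window ChIP-vs-input NB test, Simes combination per TSS region, and
#' BH correction over genes.
#'
#' @param chip,input Window x sample count matrices (rows = unique windows of
#'   \code{grid}).
#' @param grid The \code{window_grid} the counts were made on.
#' @param bin_counts Genome-wide background bins x samples (columns matching
#'   \code{cbind(chip, input)}), used for the background filter, the TMM
#'   factors and the library sizes.
#' @param config A \code{pipeline_config}.
#' @param universe Gene ids reported even when untested (default: all grid
#'   genes).
#' @return A \code{region_results} data.frame with an added \code{fdr} column.
#' @export
call_marked_genes <- function(chip, input, grid, bin_counts,
                              config = pipeline_config(),
                              universe = unique(grid$gene_id)) {
  chip <- as.matrix(chip); input <- as.matrix(input)
  uw <- unique_windows(grid)
  stopifnot(nrow(chip) == nrow(uw), nrow(input) == nrow(uw))
  all_counts <- cbind(chip, input)
  keep_min <- filter_min_count(all_counts, config$min_total_count)
  chip_sum <- rowSums(chip)
  bin_chip_sum <- rowSums(as.matrix(bin_counts)[, seq_len(ncol(chip)),
                                                drop = FALSE])
  keep_bg <- filter_global_background(chip_sum, uw$end - uw$start,
                                      bin_chip_sum,
                                      bin_size = config$bg_bin_size,
                                      min_log2fc = config$bg_min_log2fc,
                                      pseudo_count = config$pseudo_count)
  keep <- keep_min & keep_bg
  lib_sizes <- colSums(as.matrix(bin_counts))
  nf <- tmm_factors(as.matrix(bin_counts), lib_sizes)
  if (!any(keep)) {
    res <- combine_region_pvalues(
      data.frame(logFC = numeric(0), p = numeric(0),
                 method = character(0)),
      character(0), grid, universe)
  } else {
    wt <- test_windows(chip[keep, , drop = FALSE],
                       input[keep, , drop = FALSE],
                       lib_sizes = lib_sizes, norm_factors = nf,
                       fixed_dispersion = config$no_replicate_dispersion)
    res <- combine_region_pvalues(wt, uw$window_id[keep], grid, universe)
  }
  res$fdr <- NA_real_
  res$fdr[res$tested] <- bh_adjust(res$p[res$tested])
  res
}

#' Chromatin-state calling across the three marks
#'
#' Convenience wrapper over \code{\link{call_marked_genes}},
#' \code{\link{call_marks}} and \code{\link{assign_states}} for data shaped
#' like the output of \code{\link{simulate_chip_counts}}.
#'
#' @param mark_data Named list (K4, K27, K9); each element a list with
#'   \code{chip}, \code{input}, \code{grid}, \code{bin_counts}.
#' @param config A \code{pipeline_config}.
#' @param universe Gene universe (default: union over marks).
#' @return list(states = \code{state_assignment}, region_results = per-mark
#'   list, mark_calls = per-mark call tables).
#' @export
call_chromatin_states <- function(mark_data, config = pipeline_config(),
                                  universe = NULL) {
  marks <- intersect(c("K4", "K27", "K9"), names(mark_data))
  if (is.null(universe))
    universe <- sort(unique(unlist(lapply(marks, function(m)
      mark_data[[m]]$grid$gene_id))))
  region_results <- list()
  calls <- data.frame(gene_id = universe, stringsAsFactors = FALSE)
  for (m in marks) {
    d <- mark_data[[m]]
    rr <- call_marked_genes(d$chip, d$input, d$grid, d$bin_counts, config,
                            universe)
    region_results[[m]] <- rr
    mc <- call_marks(rr, config$fdr_threshold)
    calls[[m]] <- mc$bound[match(universe, mc$gene_id)]
  }
  states <- assign_states(calls)
  list(states = states, region_results = region_results, mark_calls = calls)
}
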