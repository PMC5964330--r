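#' Canonical chromatin-state labels
#'
#' The eight combinatorial states of H3K4me3 (K4), H3K27me3 (K27) and H3K9me3
#' (K9). Compound labels order the marks K4, K9, K27 ("K4/K9/K27", "K9/K27"),
#' and the level order follows the conventional display: K27, K4, K4/K27,
#' K4/K9, K4/K9/K27, K9, K9/K27, None.
#'
#' @return Character vector of the 8 state labels.
#' @export
chromatin_states <- function() {
  c("K27", "K4", "K4/K27", "K4/K9", "K4/K9/K27", "K9", "K9/K27", "None")
}

state_label <- function(k4, k27, k9) {
  parts <- c("K4"[k4], "K9"[k9], "K27"[k27])
  if (!length(parts)) "None" else paste(parts, collapse = "/")
}

#' Binary mark calls from region-level FDR
#'
#' A gene is marked when its region FDR is strictly below the threshold;
#' untested genes are never marked.
#'
#' @param region_results A \code{region_results} data.frame for one mark
#'   (columns gene_id, p, tested).
#' @param fdr_threshold Strict FDR cutoff (default 0.05).
#' @return data.frame gene_id, fdr, bound.
#' @export
call_marks <- function(region_results, fdr_threshold = 0.05) {
  fdr <- rep(NA_real_, nrow(region_results))
  fdr[region_results$tested] <- bh_adjust(region_results$p[region_results$tested])
  data.frame(gene_id = region_results$gene_id, fdr = fdr,
             bound = !is.na(fdr) & fdr < fdr_threshold,
             stringsAsFactors = FALSE)
}

#' Combinatorial chromatin-state assignment
#'
#' Maps the three binary mark calls per gene to one of the 8 states. The
#' mapping is the exhaustive truth table: (K4, K27, K9) = (T, T, F) gives
#' "K4/K27", (F, F, F) gives "None", and so on.
#'
#' @param mark_calls data.frame with columns \code{gene_id} and logical
#'   \code{K4}, \code{K27}, \code{K9}; a missing mark column counts as
#'   all-FALSE.
#' @return data.frame of class \code{state_assignment}: gene_id, K4, K27, K9,
#'   state (factor over \code{\link{chromatin_states}}).
#' @export
assign_states <- function(mark_calls) {
  stopifnot("gene_id" %in% names(mark_calls))
  for (m in c("K4", "K27", "K9"))
    if (is.null(mark_calls[[m]])) mark_calls[[m]] <- FALSE
  lab <- mapply(state_label, mark_calls$K4, mark_calls$K27, mark_calls$K9)
  out <- data.frame(gene_id = mark_calls$gene_id,
                    K4 = mark_calls$K4, K27 = mark_calls$K27,
                    K9 = mark_calls$K9,
                    state = factor(lab, levels = chromatin_states()),
                    stringsAsFactors = FALSE)
  class(out) <- c("state_assignment", "data.frame")
  out
}

#' Recover the mark booleans from a state label
#'
#' Inverse of the truth-table mapping used by \code{\link{assign_states}}.
#'
#' @param state Character vector of state labels.
#' @return data.frame with logical columns K4, K27, K9.
#' @export
state_to_marks <- function(state) {
  state <- as.character(state)
  stopifnot(all(state %in% chromatin_states()))
  parts <- strsplit(state, "/", fixed = TRUE)
  data.frame(K4 = vapply(parts, function(p) "K4" %in% p, TRUE),
             K27 = vapply(parts, function(p) "K27" %in% p, TRUE),
             K9 = vapply(parts, function(p) "K9" %in% p, TRUE))
}

#' Relative abundance of chromatin states
#'
#' @param states A \code{state_assignment} or a factor/character vector of
#'   state labels.
#' @return data.frame state, n, fraction; fractions sum to 1.
#' @export
state_abundance <- function(states) {
  s <- if (inherits(states, "state_assignment")) states$state else states
  s <- factor(as.character(s), levels = chromatin_states())
  if (!length(s)) stop("empty state assignment")
  n <- table(s)
  data.frame(state = names(n), n = as.integer(n),
             fraction = as.numeric(n) / length(s),
             stringsAsFactors = FALSE)
}

#' Average coverage profile per chromatin state
#'
#' Positionwise mean of per-gene binned coverage within each state. Profiles
#' are TSS-oriented: rows of minus-strand genes are reversed before averaging
#' (switchable). States with no member genes yield rows of NA.
#'
#' @param coverage Gene x bin coverage matrix (e.g. from
#'   \code{\link{compute_coverage}}), rows named by gene_id.
#' @param states A \code{state_assignment} covering the coverage rows.
#' @param strand Named character vector of gene strands; required when
#'   \code{orient = TRUE}.
#' @param orient Reverse minus-strand rows so profiles read 5' to 3'
#'   (default TRUE).
#' @return Matrix 8 x bins (rows = \code{\link{chromatin_states}}).
#' @export
average_profile <- function(coverage, states, strand = NULL, orient = TRUE) {
  stopifnot(!is.null(rownames(coverage)))
  if (orient) {
    if (is.null(strand)) stop("strand needed to orient profiles")
    minus <- rownames(coverage)[strand[rownames(coverage)] == "-"]
    coverage[minus, ] <- coverage[minus, rev(seq_len(ncol(coverage))),
                                  drop = FALSE]
  }
  st <- setNames(as.character(states$state), states$gene_id)
  out <- matrix(NA_real_, 8, ncol(coverage),
                dimnames = list(chromatin_states(), NULL))
  for (s in chromatin_states()) {
    members <- rownames(coverage)[st[rownames(coverage)] == s]
    members <- members[!is.na(members)]
    if (length(members))
      out[s, ] <- colMeans(coverage[members, , drop = FALSE])
  }
  out
}
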