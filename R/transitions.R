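#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Exact two-sided p for the table rbind(c(a, b), c(c, d)) by the standard
#' rule: the sum of hypergeometric point probabilities (with all margins
#' fixed) not exceeding the probability of the observed table, up to a small
#' relative tolerance. Identical to \code{stats::fisher.test()$p.value}.
#'
#' @param a,b,c_,d Nonnegative integer cell counts; rows are set/complement,
#'   columns are in-category/not.
#' @return The two-sided p-value.
#' @export
fisher_exact_p <- function(a, b, c_, d) {
  stopifnot(a >= 0, b >= 0, c_ >= 0, d >= 0)
  m <- a + c_          # total in category
  n <- b + d           # total not in category
  k <- a + b           # set size
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  dens <- dhyper(support, m, n, k)
  min(1, sum(dens[dens <= dhyper(a, m, n, k) * (1 + 1e-7)]))
}

#' Odds ratio with zero-cell correction
#'
#' Raw cross-product ratio (a d)/(b c); when any cell is zero the
#' Haldane-Anscombe +0.5 correction is applied to every cell and the result is
#' flagged.
#'
#' @inheritParams fisher_exact_p
#' @return list(or, corrected).
#' @export
odds_ratio <- function(a, b, c_, d) {
  if (any(c(a, b, c_, d) == 0)) {
    list(or = ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5)),
         corrected = TRUE)
  } else {
    list(or = (a * d) / (b * c_), corrected = FALSE)
  }
}

#' Chromatin-state transition matrix between two cell types
#'
#' Counts every universe gene into one of the 64 ordered state pairs (state in
#' cell type A, state in cell type B). Genes missing from an assignment are
#' counted as "None" with a warning.
#'
#' @param states_a,states_b \code{state_assignment} objects (or data.frames
#'   with gene_id and state).
#' @param universe Character vector of gene ids defining the background.
#' @return Object of class \code{transition_matrix}: \code{counts} (8x8
#'   integer matrix, rows = states in A), \code{transitions} (per-gene
#'   data.frame gene_id, state_a, state_b), \code{universe}.
#' @export
build_transition_matrix <- function(states_a, states_b,
                                    universe = union(states_a$gene_id,
                                                     states_b$gene_id)) {
  lookup <- function(states, who) {
    s <- setNames(as.character(states$state), states$gene_id)[universe]
    if (anyNA(s)) {
      warning(sum(is.na(s)), " universe gene(s) missing from the ", who,
              " assignment; counted as 'None'")
      s[is.na(s)] <- "None"
    }
    factor(s, levels = chromatin_states())
  }
  sa <- lookup(states_a, "first")
  sb <- lookup(states_b, "second")
  counts <- table(state_a = sa, state_b = sb)
  structure(list(counts = unclass(as.matrix(counts)),
                 transitions = data.frame(gene_id = universe,
                                          state_a = as.character(sa),
                                          state_b = as.character(sb),
                                          stringsAsFactors = FALSE),
                 universe = universe),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("transition_matrix over %d genes\n", length(x$universe)))
  print(x$counts)
  invisible(x)
}

# shared 2x2 enrichment machinery: categories is a factor over the universe,
# one level per tested category; gene_set indexes into the universe.
enrich_categories <- function(gene_set, categories, universe) {
  if (!length(gene_set)) stop("empty gene set")
  if (!all(gene_set %in% universe))
    stop("gene set contains ids outside the universe")
  gene_set <- unique(gene_set)
  n <- length(gene_set)
  N <- length(universe)
  in_set <- universe %in% gene_set
  levs <- levels(categories)
  a <- as.integer(table(categories[in_set]))
  K <- as.integer(table(categories))
  b <- n - a
  c_ <- K - a
  d <- N - n - c_
  if (n == N) {
    # degenerate: the complement is empty, there is no contrast
    or <- rep(1, length(levs)); corrected <- rep(FALSE, length(levs))
    p <- rep(1, length(levs))
  } else {
    zero <- a == 0 | b == 0 | c_ == 0 | d == 0
    or <- ifelse(zero,
                 ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5)),
                 (a * d) / (b * c_))
    corrected <- zero
    p <- vapply(seq_along(levs), function(i)
      fisher_exact_p(a[i], b[i], c_[i], d[i]), numeric(1))
  }
  out <- data.frame(category = levs, a = a, n = n, K = K, N = N,
                    odds_ratio = or, or_corrected = corrected, p = p,
                    stringsAsFactors = FALSE)
  out$fdr <- bh_adjust(out$p)
  out$significant <- out$fdr < 0.05
  out$direction <- ifelse(out$odds_ratio >= 1, "over", "under")
  rownames(out) <- NULL
  out
}

#' Gene-set enrichment over the 64 chromatin-state transitions
#'
#' For each ordered state pair, a 2x2 table contrasts the gene set with its
#' complement in the universe for membership in that transition; enrichment is
#' the odds ratio with a two-sided Fisher exact p, and BH correction is
#' applied across the 64 tests of the comparison.
#'
#' @param gene_set Character vector of gene ids (subset of the universe).
#' @param tm A \code{transition_matrix} from
#'   \code{\link{build_transition_matrix}}.
#' @return data.frame with 64 rows: state_a, state_b, a (set genes in the
#'   transition), n (set size), K (universe genes in the transition), N
#'   (universe size), odds_ratio, or_corrected, p, fdr, significant,
#'   direction.
#' @export
transition_enrichment <- function(gene_set, tm) {
  stopifnot(inherits(tm, "transition_matrix"))
  tr <- tm$transitions
  cat64 <- factor(paste(tr$state_a, tr$state_b, sep = " -> "),
                  levels = as.vector(outer(chromatin_states(),
                                           chromatin_states(),
                                           function(a, b) paste(a, b, sep = " -> "))))
  res <- enrich_categories(gene_set, cat64, tm$universe)
  parts <- strsplit(res$category, " -> ", fixed = TRUE)
  res$state_a <- vapply(parts, `[`, "", 1L)
  res$state_b <- vapply(parts, `[`, "", 2L)
  res[c("state_a", "state_b", "a", "n", "K", "N", "odds_ratio",
        "or_corrected", "p", "fdr", "significant", "direction")]
}

#' Gene-set enrichment over the 8 chromatin states of one cell type
#'
#' Same 2x2 construction as \code{\link{transition_enrichment}}, per single
#' state, with BH correction across the 8 tests.
#'
#' @param gene_set Character vector of gene ids.
#' @param states A \code{state_assignment}.
#' @param universe Gene ids defining the background (default: all assigned
#'   genes).
#' @return data.frame with 8 rows: state, a, n, K, N, odds_ratio,
#'   or_corrected, p, fdr, significant, direction.
#' @export
state_enrichment <- function(gene_set, states, universe = states$gene_id) {
  s <- setNames(as.character(states$state), states$gene_id)[universe]
  if (anyNA(s)) {
    warning(sum(is.na(s)), " universe gene(s) without a state; ",
            "counted as 'None'")
    s[is.na(s)] <- "None"
  }
  res <- enrich_categories(gene_set, factor(s, levels = chromatin_states()),
                           universe)
  names(res)[names(res) == "category"] <- "state"
  res
}

#' Per-category counts and percentages of a gene set
#'
#' Tabulates a gene set over chromatin states or transitions and reports the
#' count and the percentage of the set (one decimal), the form used for
#' statements such as "n = 93, 34.2 percent".
#'
#' @param gene_set Character vector of gene ids.
#' @param assignment A \code{state_assignment} (per-state summary) or a
#'   \code{transition_matrix} (per-transition summary).
#' @return data.frame category, n, pct.
#' @export
proportion_summary <- function(gene_set, assignment) {
  if (!length(gene_set)) stop("empty gene set")
  gene_set <- unique(gene_set)
  if (inherits(assignment, "transition_matrix")) {
    tr <- assignment$transitions
    cat_ <- paste(tr$state_a, tr$state_b, sep = " -> ")
    levs <- as.vector(outer(chromatin_states(), chromatin_states(),
                            function(a, b) paste(a, b, sep = " -> ")))
    f <- factor(cat_, levels = levs)
    ids <- tr$gene_id
  } else {
    f <- factor(as.character(assignment$state), levels = chromatin_states())
    ids <- assignment$gene_id
  }
  n <- table(f[ids %in% gene_set])
  data.frame(category = names(n), n = as.integer(n),
             pct = round(100 * as.integer(n) / length(gene_set), 1),
             stringsAsFactors = FALSE)
}
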