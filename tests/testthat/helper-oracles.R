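# Independent oracles used to freeze expected values. These deliberately use
# different algorithms (enumeration, explicit sorting, per-read scans) from
# the implementation they check.

# step-up BH by direct enumeration of the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    k <- which(o == i)  # rank of p[i]
    adj[i] <- min(1, min(n * p[o][k:n] / (k:n)))
  }
  adj
}

oracle_simes <- function(p) {
  m <- length(p)
  min(vapply(seq_len(m), function(i) m * sort(p)[i] / i, numeric(1)))
}

# two-sided Fisher p by full enumeration of all tables with the same margins
oracle_fisher <- function(a, b, c_, d) {
  K <- a + c_; n <- a + b; N <- a + b + c_ + d
  support <- max(0, n + K - N):min(n, K)
  probs <- vapply(support, function(x) {
    exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n))
  }, numeric(1))
  obs <- probs[support == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# TMM by explicit sort-and-drop trimming (unweighted), ref chosen by upper
# quartile of count rates
oracle_tmm <- function(x, lib = colSums(x), trim_m = 0.3, trim_a = 0.05) {
  rates <- sweep(x, 2, lib, "/")
  uq <- apply(rates, 2, quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- sapply(seq_len(ncol(x)), function(s) {
    if (s == ref) return(1)
    keep <- x[, s] > 0 & x[, ref] > 0
    m <- log2(rates[keep, s] / rates[keep, ref])
    a <- 0.5 * log2(rates[keep, s] * rates[keep, ref])
    n <- length(m)
    drop_m <- floor(n * trim_m)
    drop_a <- floor(n * trim_a)
    # two-sided rank rule (tied values share a fate, as in the documentation)
    keep_m <- which(rank(m) >= drop_m + 1 & rank(m) <= n - drop_m)
    keep_a <- which(rank(a) >= drop_a + 1 & rank(a) <= n - drop_a)
    2 ^ mean(m[intersect(keep_m, keep_a)])
  })
  f / exp(mean(log(f)))
}

# exact two-sided Wilcoxon rank-sum p by enumerating all group assignments
oracle_wilcoxon <- function(x, y) {
  all_v <- c(x, y)
  m <- length(x)
  idx <- combn(length(all_v), m)
  w_obs <- sum(rank(all_v)[seq_len(m)]) - m * (m + 1) / 2
  ws <- apply(idx, 2, function(i) sum(rank(all_v)[i]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# per-read brute-force window counting (0-based half-open throughout)
oracle_count <- function(reads, windows, fragment_len) {
  counts <- setNames(numeric(nrow(windows)), windows$window_id)
  for (i in seq_len(nrow(reads))) {
    if (reads$strand[i] == "+") {
      fs <- reads$start[i]; fe <- fs + fragment_len
    } else {
      fe <- reads$start[i] + 1; fs <- max(0, fe - fragment_len)
    }
    hit <- windows$chrom == reads$chrom[i] &
      windows$start < fe & windows$end > fs
    counts[hit] <- counts[hit] + 1
  }
  counts
}

# fixture: a state_assignment with given labels
make_states <- function(gene_ids, labels) {
  marks <- state_to_marks(labels)
  assign_states(data.frame(gene_id = gene_ids, K4 = marks$K4,
                           K27 = marks$K27, K9 = marks$K9,
                           stringsAsFactors = FALSE))
}

# fixture: transition_matrix with prescribed per-pair gene counts; `pairs` is
# a data.frame(state_a, state_b, n)
make_transitions <- function(pairs) {
  la <- rep(pairs$state_a, pairs$n)
  lb <- rep(pairs$state_b, pairs$n)
  ids <- sprintf("g%05d", seq_along(la))
  build_transition_matrix(make_states(ids, la), make_states(ids, lb), ids)
}
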