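test_that("transition matrices tally every universe gene exactly once", {
  # one gene per state, identical in both cell types -> diagonal of ones
  ids <- sprintf("g%d", 1:8)
  st <- make_states(ids, chromatin_states())
  tm <- build_transition_matrix(st, st, ids)
  expect_equal(unname(diag(tm$counts)), rep(1L, 8))
  expect_equal(sum(tm$counts), 8L)
  expect_equal(sum(tm$counts) - sum(diag(tm$counts)), 0L)

  set.seed(41)
  n <- 1000
  la <- sample(chromatin_states(), n, TRUE)
  lb <- sample(chromatin_states(), n, TRUE)
  ids <- sprintf("g%d", 1:n)
  tm2 <- build_transition_matrix(make_states(ids, la), make_states(ids, lb),
                                 ids)
  expect_equal(sum(tm2$counts), n)
  # brute-force tally
  for (i in sample(64, 10)) {
    sa <- chromatin_states()[(i - 1) %% 8 + 1]
    sb <- chromatin_states()[(i - 1) %/% 8 + 1]
    expect_equal(unname(tm2$counts[sa, sb]), sum(la == sa & lb == sb))
  }

  # genes missing from an assignment count as None, with a warning
  expect_warning(expect_warning(
    tm3 <- build_transition_matrix(make_states("g1", "K4"),
                                   make_states("g1", "K4"),
                                   universe = c("g1", "g2")),
    "None"), "None")
  expect_equal(unname(tm3$counts["None", "None"]), 1L)
})

test_that("transition enrichment reproduces the 2x2 arithmetic and Fisher p", {
  # universe 100 genes, 20 in the K4 -> K4/K27 transition; a 10-gene set has 6
  labels_b <- rep(c("K4/K27", "K4"), c(20, 80))
  tm <- make_transitions(data.frame(state_a = "K4",
                                    state_b = c("K4/K27", "K4"),
                                    n = c(20, 80)))
  gene_set <- tm$universe[c(1:6, 30:33)]  # 6 in the transition, 4 outside
  res <- transition_enrichment(gene_set, tm)
  expect_equal(nrow(res), 64)
  row <- res[res$state_a == "K4" & res$state_b == "K4/K27", ]
  expect_equal(row$a, 6L)
  expect_equal(row$K, 20L)
  expect_equal(row$odds_ratio, (6 * 76) / (4 * 14))
  expect_equal(row$p, oracle_fisher(6, 4, 14, 76))
  expect_equal(row$p, fisher.test(rbind(c(6, 4), c(14, 76)))$p.value)
  # per-transition set counts add up to the set size
  expect_equal(sum(res$a), length(gene_set))

  # degenerate set = universe: no contrast
  res_all <- transition_enrichment(tm$universe, tm)
  expect_true(all(res_all$odds_ratio == 1))
  expect_true(all(res_all$p == 1))

  expect_error(transition_enrichment(character(0), tm), "empty")
  expect_error(transition_enrichment("nonexistent", tm), "universe")
})

test_that("state enrichment matches hand arithmetic and a null set is flat", {
  # universe 1000 with 100 bivalent; set of 50 with 20 bivalent -> OR 7.25
  labels <- rep(c("K4/K27", "K4"), c(100, 900))
  ids <- sprintf("g%04d", 1:1000)
  st <- make_states(ids, labels)
  gene_set <- c(ids[1:20], ids[101:130])
  res <- state_enrichment(gene_set, st)
  expect_equal(nrow(res), 8)
  row <- res[res$state == "K4/K27", ]
  expect_equal(row$odds_ratio, (20 * 870) / (30 * 80))
  expect_equal(row$p, oracle_fisher(20, 30, 80, 870))

  # set proportioned exactly like the universe -> all defined ORs are 1
  prop_set <- c(ids[1:10], ids[101:190])  # 10% bivalent, like the universe
  res2 <- state_enrichment(prop_set, st)
  defined <- res2[res2$K > 0, ]
  expect_true(all(abs(defined$odds_ratio - 1) < 1e-12))
})

test_that("odds ratios get the +0.5 correction only on zero cells", {
  or0 <- odds_ratio(0, 10, 5, 85)
  expect_true(or0$corrected)
  expect_equal(or0$or, (0.5 * 85.5) / (10.5 * 5.5))
  or1 <- odds_ratio(6, 4, 14, 76)
  expect_false(or1$corrected)
})

test_that("Fisher p equals brute-force enumeration over random small tables", {
  set.seed(42)
  for (i in 1:100) {
    N <- sample(10:200, 1)
    K <- sample(seq_len(N - 1), 1)
    n <- sample(seq_len(N - 1), 1)
    a <- sample(max(0, n + K - N):min(n, K), 1)
    b <- n - a; c_ <- K - a; d <- N - n - c_
    expect_equal(fisher_exact_p(a, b, c_, d), oracle_fisher(a, b, c_, d),
                 tolerance = 1e-12)
    expect_equal(fisher_exact_p(a, b, c_, d),
                 fisher.test(rbind(c(a, b), c(c_, d)))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("odds ratio is invariant to the double swap of set and category", {
  set.seed(43)
  for (i in 1:25) {
    t_ <- sample(1:30, 4, replace = TRUE)
    or1 <- odds_ratio(t_[1], t_[2], t_[3], t_[4])$or
    or2 <- odds_ratio(t_[4], t_[3], t_[2], t_[1])$or
    expect_equal(or1, or2)
  }
})

test_that("proportion summaries report counts and one-decimal percentages", {
  # 272-gene set with 93 in K4 -> K4
  tm <- make_transitions(data.frame(state_a = c("K4", "K4", "None"),
                                    state_b = c("K4", "K4/K27", "None"),
                                    n = c(93, 59, 120)))
  gene_set <- tm$universe
  ps <- proportion_summary(gene_set, tm)
  expect_equal(sum(ps$n), 272L)
  expect_equal(ps$pct[ps$category == "K4 -> K4"], 34.2)
  expect_equal(ps$pct[ps$category == "K4 -> K4/K27"], 21.7)
  expect_equal(ps$pct[ps$category == "K27 -> K9"], 0)

  st <- make_states(sprintf("g%d", 1:160), rep(c("K4/K27", "K4"), c(53, 107)))
  ps2 <- proportion_summary(st$gene_id, st)
  expect_equal(ps2$pct[ps2$category == "K4/K27"], 33.1)
  expect_equal(ps2$n[ps2$category == "K9"], 0L)
  expect_equal(ps2$pct[ps2$category == "K9"], 0)
})
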