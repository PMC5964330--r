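test_that("RPKM follows its definition and scaling laws", {
  expect_equal(unname(compute_rpkm(matrix(100), lengths = 1000,
                                   lib_sizes = 1e6)[1, 1]), 100)
  expect_equal(unname(compute_rpkm(matrix(0), 1000, 1e6)[1, 1]), 0)
  # doubling the library size halves RPKM
  x <- matrix(c(50, 50), 1, 2)
  r <- compute_rpkm(x, lengths = 500, lib_sizes = c(1e6, 2e6))
  expect_equal(r[1, 1], 2 * r[1, 2])
  expect_error(compute_rpkm(matrix(1), 0, 1e6), "length")
})

test_that("silent classification agrees between log and linear forms", {
  expect_true(classify_silent(0.9))     # log2(1.9) = 0.926 < 1
  expect_false(classify_silent(1.0))    # log2(2) = 1, strict <
  expect_true(classify_silent(0))
  set.seed(51)
  x <- runif(500, 0, 3)
  expect_equal(classify_silent(x), x < 1)
})

test_that("per-state expression tests match exact rank enumeration", {
  # {1,2,3} vs {4,5,6}: exact two-sided p = 0.1
  genes <- sprintf("g%d", 1:6)
  st <- make_states(genes, rep(c("K4", "None"), each = 3))
  expr <- setNames(c(1, 2, 3, 4, 5, 6), genes)
  res <- state_expression_test(expr, st)
  expect_equal(res$p[res$state == "K4"], 0.1)
  expect_equal(res$p[res$state == "K4"], oracle_wilcoxon(1:3, 4:6))
  expect_equal(res$median[res$state == "K4"], 2)
  expect_equal(res$n[res$state == "None"], 3L)

  # identical distributions -> p in the null region
  st2 <- make_states(sprintf("g%d", 1:8), rep(c("K27", "None"), each = 4))
  same <- setNames(rep(c(1, 2, 3, 4), 2), sprintf("g%d", 1:8))
  res2 <- suppressWarnings(state_expression_test(same, st2))
  expect_gte(res2$p[res2$state == "K27"], 0.9)

  # states with < 2 members: statistics reported, p omitted
  st3 <- make_states(c("a", "b", "c"), c("K9", "K4", "K4"))
  res3 <- state_expression_test(setNames(1:3, c("a", "b", "c")), st3)
  expect_true(is.na(res3$p[res3$state == "K9"]))
  expect_equal(res3$median[res3$state == "K9"], 1)
})

test_that("implementation Wilcoxon equals enumeration for small groups", {
  set.seed(52)
  for (i in 1:20) {
    m <- sample(2:8, 1); n <- sample(2:8, 1)
    vals <- sample(1000, m + n)  # no ties
    p_impl <- wilcox.test(vals[1:m], vals[(m + 1):(m + n)])$p.value
    expect_equal(p_impl, oracle_wilcoxon(vals[1:m], vals[(m + 1):(m + n)]))
  }
})

test_that("simulated K4-high expression orders the state medians", {
  st <- simulate_states(sprintf("g%d", 1:2000), seed = 53)
  ex <- simulate_expression(st, seed = 54)
  expr <- setNames(ex$log_expr, st$gene_id)
  res <- state_expression_test(expr, st)
  k4_med <- res$median[res$state == "K4"]
  expect_gt(k4_med, median(expr))
  expect_lt(res$p[res$state == "K4"], 0.01)
  expect_gt(k4_med, res$median[res$state == "None"])
})

test_that("regulated-gene selection implements both set rules", {
  up <- c("a", "b", "c"); down <- c("d", "e")
  # no UB subtraction, everything enriched -> identity
  sel <- select_stress_regulated(up, down, character(0), c(up, down))
  expect_equal(sel$up, sort(up))
  expect_equal(sel$down, sort(down))

  sel2 <- select_stress_regulated(c("a", "b", "c"), character(0),
                                  ub_de = "b", trap_enriched = c("a", "b"))
  expect_equal(sel2$up, "a")

  # alternative rule: only UB genes NOT enriched are subtracted
  sel3 <- select_stress_regulated(c("a", "b", "c"), character(0),
                                  ub_de = c("b", "c"), trap_enriched = "b",
                                  rule = "subtract_filtered")
  expect_equal(sel3$up, c("a", "b"))

  expect_error(select_stress_regulated(c("a", "b"), c("b", "c"),
                                       character(0), character(0)),
               "overlap")

  # random sets equal an independent set-expression oracle
  set.seed(55)
  for (i in 1:10) {
    pool <- sprintf("g%d", 1:50)
    tu <- sample(pool, 15); ub <- sample(pool, 10); en <- sample(pool, 25)
    got <- select_stress_regulated(tu, character(0), ub, en)$up
    expect_setequal(got, pool[pool %in% tu & !(pool %in% ub) & pool %in% en])
  }
})
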