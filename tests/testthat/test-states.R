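test_that("mark calls use a strict FDR boundary and skip untested genes", {
  rr <- data.frame(gene_id = c("a", "b", "c"),
                   p = c(0.049, 0.05, NA), n_windows = c(1L, 1L, 0L),
                   max_logfc = c(3, 3, NA),
                   tested = c(TRUE, TRUE, FALSE), method = "ql_ftest")
  # single-gene BH leaves p unchanged; feed FDRs directly via 1-gene families
  mc <- call_marks(rr[1, ], 0.05)
  expect_true(mc$bound)
  mc2 <- call_marks(rr[2, ], 0.05)
  expect_false(mc2$bound)
  mc3 <- call_marks(rr, 0.05)
  expect_false(mc3$bound[mc3$gene_id == "c"])  # untested, never bound

  set.seed(31)
  n <- 100
  rr_big <- data.frame(gene_id = sprintf("g%d", 1:n), p = runif(n),
                       n_windows = 1L, max_logfc = 1, tested = TRUE,
                       method = "ql_ftest")
  mc4 <- call_marks(rr_big, 0.2)
  expect_equal(mc4$bound, bh_adjust(rr_big$p) < 0.2)
})

test_that("state assignment is a bijection on the 8 mark combinations", {
  combos <- expand.grid(K4 = c(FALSE, TRUE), K27 = c(FALSE, TRUE),
                        K9 = c(FALSE, TRUE))
  combos$gene_id <- sprintf("g%d", 1:8)
  st <- assign_states(combos)
  expect_setequal(as.character(st$state), chromatin_states())
  expect_equal(as.character(st$state[!combos$K4 & !combos$K27 & !combos$K9]),
               "None")
  expect_equal(as.character(st$state[combos$K4 & combos$K27 & !combos$K9]),
               "K4/K27")
  expect_equal(as.character(st$state[combos$K4 & combos$K27 & combos$K9]),
               "K4/K9/K27")
  # round-trip: labels back to booleans recovers the input
  back <- state_to_marks(st$state)
  expect_equal(back$K4, combos$K4)
  expect_equal(back$K27, combos$K27)
  expect_equal(back$K9, combos$K9)
})

test_that("missing mark columns default to unmarked", {
  st <- assign_states(data.frame(gene_id = "g", K4 = TRUE))
  expect_equal(as.character(st$state), "K4")
})

test_that("state abundance fractions sum to one and recover known proportions", {
  st <- make_states(sprintf("g%d", 1:8), chromatin_states())
  ab <- state_abundance(st)
  expect_equal(ab$fraction, rep(0.125, 8))

  all_k4 <- make_states(sprintf("g%d", 1:5), rep("K4", 5))
  ab2 <- state_abundance(all_k4)
  expect_equal(ab2$fraction[ab2$state == "K4"], 1)
  expect_equal(sum(ab2$fraction), 1, tolerance = 1e-12)
  expect_equal(sum(ab2$n), 5L)

  labels <- rep(c("K4", "None", "K9/K27"), c(50, 30, 20))
  ab3 <- state_abundance(make_states(sprintf("g%d", 1:100), labels))
  expect_equal(ab3$fraction[ab3$state == "K4"], 0.5)
  expect_equal(ab3$fraction[ab3$state == "K9/K27"], 0.2)
})

test_that("average profiles are per-state means, TSS-oriented", {
  genes <- sprintf("g%d", 1:4)
  cov <- matrix(3, 4, 10, dimnames = list(genes, NULL))
  st <- make_states(genes, c("K4", "K4", "K27", "None"))
  strand <- setNames(rep("+", 4), genes)
  prof <- average_profile(cov, st, strand)
  expect_true(all(prof["K4", ] == 3))
  expect_true(all(is.na(prof["K9", ])))  # no member genes -> NA, not 0

  # single gene per state: profile equals that gene's (oriented) coverage
  ramp <- matrix(1:10, 1, 10, dimnames = list("g1", NULL))
  st1 <- make_states("g1", "K4")
  expect_equal(unname(average_profile(ramp, st1, c(g1 = "+"))["K4", ]),
               1:10)
  expect_equal(unname(average_profile(ramp, st1, c(g1 = "-"))["K4", ]),
               10:1)
})

test_that("simulated TSS-centered bumps peak at the profile center", {
  sim <- simulate_annotation(100, seed = 33)
  st <- make_states(sim$regions$gene_id, rep("K4/K27", 100))
  chip <- simulate_chip_counts(sim, st, sim_config(n_genes = 100),
                               coverage = TRUE, seed = 34)
  strand <- setNames(sim$regions$strand, sim$regions$gene_id)
  smooth <- function(x, k) as.numeric(stats::filter(x, rep(1 / k, k)))
  # K4 is sharply TSS-centered: smoothed peak within 50 bp of the center
  prof_k4 <- smooth(average_profile(chip$K4$coverage, st, strand)["K4/K27", ],
                    21)
  center <- ncol(chip$K4$coverage) / 2
  expect_lte(abs(which.max(prof_k4) - center), 5)
  # K27 co-occurring with K4 is broader but still TSS-centered
  prof_k27 <- smooth(average_profile(chip$K27$coverage, st,
                                     strand)["K4/K27", ], 51)
  expect_lte(abs(which.max(prof_k27) - center), 30)
  # and clearly elevated at the center relative to the region edge
  expect_gt(prof_k27[center], 1.5 * mean(prof_k27[100:200]))
})
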