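test_that("MAD filter fails only the low tail, strictly", {
  x <- c(10, 10.2, 9.8, 10.1, 9.9, 10, 10.3, 4)
  metrics <- data.frame(nucleus_id = sprintf("n%d", 1:8),
                        log_libsize = x, log_genes = rep(8, 8))
  res <- suppressWarnings(mad_qc_filter(metrics))
  expect_equal(res$pass, c(rep(TRUE, 7), FALSE))

  # value exactly at median - 3 MAD passes (strict "more than")
  y <- c(1, 2, 3, 4, 5)
  thr <- median(y) - 3 * mad(y)
  m2 <- data.frame(nucleus_id = sprintf("n%d", 1:6),
                   log_libsize = c(y, thr), log_genes = 1)
  res2 <- suppressWarnings(mad_qc_filter(m2))
  expect_true(res2$pass[6])

  # all-identical metrics: MAD 0, all pass with a warning
  m3 <- data.frame(nucleus_id = sprintf("n%d", 1:5),
                   log_libsize = rep(2, 5), log_genes = rep(3, 5))
  expect_warning(expect_warning(res3 <- mad_qc_filter(m3), "MAD"), "MAD")
  expect_true(all(res3$pass))
})

test_that("MAD filter is scale-equivariant", {
  set.seed(61)
  m <- data.frame(nucleus_id = sprintf("n%d", 1:30),
                  log_libsize = rnorm(30, 10), log_genes = rnorm(30, 7))
  base <- mad_qc_filter(m)$pass
  m2 <- m
  m2$log_libsize <- m$log_libsize * 3.7
  m2$log_genes <- m$log_genes * 3.7
  expect_equal(mad_qc_filter(m2)$pass, base)
})

test_that("89 of 98 synthetic nuclei pass when 9 outliers are planted", {
  for (s in c(1, 7, 19)) {
    sim <- simulate_nuclei(98, 9, seed = s)
    qc <- mad_qc_filter(sim$metrics)
    expect_equal(sum(qc$pass), 89)
    expect_equal(qc$pass, !sim$truth_outlier)
  }
  all_in <- simulate_nuclei(40, 0, seed = 2)
  expect_true(all(mad_qc_filter(all_in$metrics)$pass))
})

test_that("variance decomposition recovers planted highly variable genes", {
  set.seed(62)
  n_genes <- 5000
  means <- runif(n_genes, 1, 8)
  trend <- 2 / (1 + exp(means - 4)) + 0.2   # smooth decreasing trend
  n_obs <- 100
  vars <- trend * rchisq(n_genes, df = n_obs - 1) / (n_obs - 1)
  planted <- sample(n_genes, 200)
  vars[planted] <- vars[planted] + 2.0
  res <- hvg_decompose(means, vars, n_obs = n_obs)
  expect_gte(mean(res$hvg[planted]), 0.9)
  expect_lt(mean(res$hvg[-planted]), 0.05)

  # genes exactly on a flat trend: no biological variance, no HVGs
  flat <- hvg_decompose(runif(500, 1, 8), rep(1, 500), n_obs = n_obs)
  expect_true(all(abs(flat$biological) < 1e-6))
  expect_false(any(flat$hvg))

  # biological component invariant to shifting total and trend together
  res_shift <- hvg_decompose(means, vars + 5, n_obs = n_obs)
  expect_equal(res_shift$biological, res$biological, tolerance = 0.05)

  expect_error(hvg_decompose(means, vars, n_obs, span = 0), "span")
  expect_error(hvg_decompose(runif(10), runif(10), n_obs), "50")
})

test_that("HVG correlations are exact for monotone pairs and reproducible", {
  set.seed(63)
  x <- seq_len(20)
  mat <- rbind(a = x, b = x^2 + 0.1, c = rnorm(20), d = rep(1, 20))
  colnames(mat) <- sprintf("cell%d", 1:20)
  res <- hvg_correlations(mat, c("a", "b", "c"), n_permutations = 199,
                          seed = 9)
  ab <- res[res$gene1 == "a" & res$gene2 == "b", ]
  expect_equal(ab$rho, 1)
  expect_equal(ab$p, 1 / 200)

  res2 <- hvg_correlations(mat, c("a", "b", "c"), n_permutations = 199,
                           seed = 9)
  expect_equal(res, res2)

  # constant gene pairs are skipped with a flag
  resd <- hvg_correlations(mat, c("a", "d"), n_permutations = 100, seed = 1)
  expect_true(resd$skipped)

  # rho matches a brute-force rank correlation on ties-free data
  brute <- cor(rank(mat["a", ]), rank(mat["c", ]))
  ac <- res[res$gene1 == "a" & res$gene2 == "c", ]
  expect_equal(ac$rho, brute)
})
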