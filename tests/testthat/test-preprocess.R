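test_that("detection filter keeps exactly the rule-satisfying proteins", {
  d <- toy_design()
  # observed-value counts per condition, one row per protein
  counts <- rbind(c(3, 0, 0), c(1, 1, 1), c(0, 3, 3), c(2, 2, 2))
  m <- counts_matrix(counts, d)
  f3 <- filter_detected(m, d, min_valid = 3)
  expect_equal(f3$proteins$protein_id, c("P1", "P3"))
  f1 <- filter_detected(m, d, min_valid = 1)
  expect_equal(nrow(f1$values), 4)

  # a protein observed nowhere is removed under any rule
  m0 <- counts_matrix(rbind(c(0, 0, 0), c(1, 0, 0)), d)
  expect_equal(filter_detected(m0, d, 1)$proteins$protein_id, "P2")
})

test_that("per-condition identification counts ride along as a side table", {
  d <- toy_design()
  counts <- rbind(c(3, 0, 0), c(1, 1, 1), c(0, 3, 3), c(2, 2, 2))
  m <- counts_matrix(counts, d)
  f1 <- filter_detected(m, d, min_valid = 1)
  expect_equal(attr(f1, "id_counts"), c(KPC = 3, PSC = 3, CoC = 3))
  f3 <- filter_detected(m, d, min_valid = 3)
  expect_equal(attr(f3, "id_counts"), c(KPC = 1, PSC = 1, CoC = 1))
})

test_that("detection filter is idempotent and validates its rule", {
  d <- toy_design()
  sim <- simulate_lfq(sim_config(n_proteins = 150, seed = 31))
  once <- filter_detected(sim$matrix, sim$design, 3)
  twice <- filter_detected(once, sim$design, 3)
  expect_identical(once$values, twice$values)
  expect_error(filter_detected(sim$matrix, sim$design, 4),
               class = "evlfq_config_error")
})

test_that("log2 transform inverts exactly and preserves the mask", {
  set.seed(41)
  v <- matrix(2^stats::rnorm(60, 20, 3), 10, 6)
  v[sample(60, 12)] <- NA
  m <- toy_matrix(v)
  lg <- log2_transform(m)
  expect_identical(lg$stage, "log2")
  expect_identical(is.na(lg$values), is.na(m$values))
  expect_equal(2^lg$values, m$values, tolerance = 1e-12)
  expect_equal(log2_transform(toy_matrix(matrix(8, 1, 1)))$values[1, 1], 3)
  expect_equal(log2_transform(toy_matrix(matrix(1, 1, 1)))$values[1, 1], 0)
})

test_that("imputation fills only missing cells from the downshifted Gaussian", {
  col <- c(10, 12, 14, NA, NA)
  v <- cbind(A = col, B = c(5, 6, 7, 8, 9))
  m <- toy_matrix(v, stage = "log2")
  im <- impute_mnar(m, seed = 1)
  expect_identical(im$stage, "imputed")
  expect_equal(sum(is.na(im$values)), 0)
  expect_identical(im$values[1:3, "A"], m$values[1:3, "A"])
  expect_identical(im$values[, "B"], m$values[, "B"])

  # analytic target for column A: Normal(12 - 1.8*2, (0.3*2)^2)
  draws <- replicate(400, {
    x <- impute_mnar(m, seed = NULL)
    x$values[4:5, "A"]
  })
  expect_lt(abs(mean(draws) - 8.4), 3 * 0.6 / sqrt(length(draws)))
  expect_lt(abs(stats::sd(draws) - 0.6) / 0.6, 0.05)
})

test_that("matrix without missing cells passes through imputation unchanged", {
  v <- matrix(rnorm(30, 20), 5, 6)
  m <- toy_matrix(v, stage = "log2")
  im <- impute_mnar(m, seed = 3)
  expect_identical(im$values, m$values)
})

test_that("zero downshift with vanishing width converges to the scope mean", {
  v <- cbind(A = c(10, 12, 14, NA))
  m <- toy_matrix(v, stage = "log2")
  im <- impute_mnar(m, width = 1e-9, downshift = 0, seed = 5)
  expect_equal(im$values[4, "A"], 12, tolerance = 1e-6)
})

test_that("imputation is reproducible under a fixed seed and errors on thin scopes", {
  sim <- simulate_lfq(sim_config(n_proteins = 100, seed = 51))
  lg <- log2_transform(filter_detected(sim$matrix, sim$design, 3))
  a <- impute_mnar(lg, seed = 99)
  b <- impute_mnar(lg, seed = 99)
  expect_identical(a$values, b$values)

  thin <- toy_matrix(cbind(A = c(1, NA, NA), B = c(1, 2, 3)), stage = "log2")
  expect_error(impute_mnar(thin), "A", class = "evlfq_data_error")
})

test_that("per-sample imputed values match the stated Normal in distribution", {
  # one column with known observed mean/sd and many missing cells
  n_miss <- 10000
  v <- cbind(A = c(10, 12, 14, rep(NA, n_miss)),
             B = rep(c(5, 6), length.out = n_miss + 3))
  m <- toy_matrix(v, stage = "log2")
  im <- impute_mnar(m, seed = 7)
  imp <- im$values[-(1:3), "A"]
  ks <- suppressWarnings(stats::ks.test(imp, "pnorm", mean = 8.4, sd = 0.6))
  expect_gt(ks$p.value, 0.01)
})
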