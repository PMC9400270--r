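# Brute-force one-way ANOVA oracle for a single row: explicit sums of squares.
anova_row_oracle <- function(values, condition) {
  groups <- split(values, condition)
  k <- length(groups)
  N <- length(values)
  grand <- mean(values)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = F, p = stats::pf(F, k - 1, N - k, lower.tail = FALSE))
}

test_that("hand-worked instance gives F = 31 with df (2, 6)", {
  d <- toy_design()
  v <- matrix(c(1, 2, 3, 2, 3, 4, 7, 8, 9), 1, 9)
  colnames(v) <- d$sample
  res <- anova_oneway(toy_matrix(v, stage = "normalized"), d)
  expect_equal(res$F, 31, tolerance = 1e-12)
  expect_equal(attr(res, "df"), c(df1 = 2, df2 = 6))
  expect_equal(res$p, stats::pf(31, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(res$mean_KPC, 2)
  expect_equal(res$mean_CoC, 8)
})

test_that("identical groups give F = 0, p = 1", {
  d <- toy_design()
  v <- matrix(rep(c(1, 2, 3), 3), 1, 9)
  colnames(v) <- d$sample
  res <- anova_oneway(toy_matrix(v, stage = "normalized"), d)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_false(res$degenerate)
})

test_that("degenerate rows are handled as documented", {
  d <- toy_design()
  # zero within- and between-group variance
  v1 <- matrix(5, 1, 9); colnames(v1) <- d$sample
  r1 <- anova_oneway(toy_matrix(v1, stage = "normalized"), d)
  expect_equal(r1$F, 0); expect_equal(r1$p, 1); expect_false(r1$degenerate)
  # zero within-group variance, non-zero between
  v2 <- matrix(rep(c(1, 2, 3), each = 3), 1, 9); colnames(v2) <- d$sample
  r2 <- anova_oneway(toy_matrix(v2, stage = "normalized"), d)
  expect_equal(r2$p, 0); expect_true(r2$degenerate)
})

test_that("vectorized ANOVA matches oracle and oneway.test on random instances", {
  d <- toy_design()
  set.seed(71)
  n <- 300
  v <- matrix(rnorm(n * 9), n, 9)
  colnames(v) <- d$sample
  res <- anova_oneway(toy_matrix(v, stage = "normalized"), d)
  for (i in sample(n, 60)) {
    oracle <- anova_row_oracle(v[i, ], d$condition)
    expect_equal(res$F[i], oracle$F, tolerance = 1e-10)
    expect_equal(res$p[i], oracle$p, tolerance = 1e-10)
    ow <- stats::oneway.test(y ~ g,
                             data = data.frame(y = v[i, ], g = d$condition),
                             var.equal = TRUE)
    expect_equal(res$F[i], unname(ow$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], unname(ow$p.value), tolerance = 1e-10)
  }
})

test_that("unbalanced designs are computed correctly", {
  d <- sample_design(paste0("s", 1:7), c("A", "A", "A", "B", "B", "C", "C"))
  v <- matrix(c(4, 6, 5, 10, 12, 1, 3), 1, 7)
  colnames(v) <- d$sample
  res <- anova_oneway(toy_matrix(v, stage = "normalized"), d)
  oracle <- anova_row_oracle(v[1, ], d$condition)
  expect_equal(res$F, oracle$F, tolerance = 1e-12)
})

test_that("BH adjustment matches the hand-worked step-up and its invariants", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # permutation equivariance: q follows its p
  set.seed(72)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  # monotone non-decreasing in p-rank, capped at 1
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "evlfq_config_error")
  expect_error(bh_adjust(c(0.5, -0.1)), class = "evlfq_config_error")
})

test_that("significance flag equals q < alpha", {
  d <- toy_design()
  set.seed(73)
  v <- matrix(rnorm(200 * 9), 200, 9)
  v[1:20, 7:9] <- v[1:20, 7:9] + 4
  colnames(v) <- d$sample
  res <- anova_oneway(toy_matrix(v, stage = "normalized"), d, alpha = 0.05)
  expect_identical(res$significant, res$q < 0.05)
  expect_true(all(res$F >= 0))
})

test_that("single-replicate conditions are refused at the differential stage", {
  d <- suppressWarnings(sample_design(paste0("s", 1:5),
                                      c("A", "A", "B", "B", "C")))
  v <- matrix(rnorm(10), 2, 5)
  colnames(v) <- d$sample
  expect_error(anova_oneway(toy_matrix(v, stage = "normalized"), d),
               "C", class = "evlfq_config_error")
})
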