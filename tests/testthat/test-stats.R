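test_that("t-tests match their textbook forms and degenerate conventions", {
  r <- ttest_zero(c(-1, 0, 1))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  x <- c(3, 4, 5); y <- c(3, 4, 5)
  expect_equal(ttest_ind(x, y)$statistic, 0)

  set.seed(1)
  a <- rnorm(12, 1); b <- rnorm(9)
  expect_equal(ttest_ind(a, b)$statistic, bf_pooled_t(a, b), tolerance = 1e-10)
  # one-sample statistic from the definition
  expect_equal(ttest_zero(a)$statistic, mean(a) / (sd(a) / sqrt(length(a))),
               tolerance = 1e-10)
  # paired equals one-sample on differences
  c2 <- rnorm(12, 0.5)
  expect_equal(ttest_paired(a, c2)$statistic, ttest_zero(a - c2)$statistic,
               tolerance = 1e-10)

  expect_message(r0 <- ttest_ind(c(1, 1), c(1, 1)), "p = 1")
  expect_equal(r0$p_value, 1)
})

test_that("the mixed ANOVA matches a brute-force sums-of-squares oracle", {
  set.seed(2)
  make_data <- function(fun) {
    expand_df <- expand.grid(subject = 1:10, day = c("d1", "d2", "d3"))
    expand_df$group <- ifelse(expand_df$subject <= 5, "UP", "DOWN")
    expand_df$value <- fun(expand_df)
    expand_df
  }
  for (rep in 1:5) {
    d <- make_data(function(df) rnorm(nrow(df)))
    got <- rm_anova_mixed(d)
    want <- bf_mixed_anova(d)
    expect_equal(got$F, want$F, tolerance = 1e-10)
  }

  # a pure interaction pattern: main effects near zero, interaction large
  d <- make_data(function(df) {
    sgn <- ifelse(df$group == "UP", 1, -1)
    lvl <- c(d1 = -1, d2 = 0, d3 = 1)[df$day]
    sgn * lvl + rnorm(nrow(df), 0, 0.05)
  })
  out <- rm_anova_mixed(d)
  expect_lt(out$F[out$effect == "group"], 1)
  expect_gt(out$F[out$effect == "group:day"], 50)

  # constant data: all F reported as zero by convention
  d0 <- make_data(function(df) rep(1, nrow(df)))
  out0 <- rm_anova_mixed(d0)
  expect_equal(out0$F, rep(0, 3))

  expect_error(rm_anova_mixed(d[-1, ]), "balanced")
})

test_that("Pearson correlation matches the closed form", {
  x <- c(1, 2, 4, 5, 9)
  y <- c(2, 3, 3, 6, 10)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  out <- pearson_corr(x, y)
  expect_equal(out$effect, r_hand, tolerance = 1e-12)
  expect_equal(pearson_corr(x, x)$effect, 1)
  expect_equal(pearson_corr(x, -2 * x)$effect, -1)
  expect_error(pearson_corr(x, rep(1, 5)), "zero-variance")
})

test_that("Benjamini-Hochberg step-up matches the hand computation", {
  out <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(out$reject))
  expect_false(any(fdr_bh(rep(1, 6), 0.05)$reject))
  # rejections are non-decreasing in q
  p <- c(0.001, 0.01, 0.02, 0.2, 0.6)
  n_rej <- vapply(c(0.01, 0.05, 0.1, 0.25), function(q) sum(fdr_bh(p, q)$reject),
                  numeric(1))
  expect_true(all(diff(n_rej) >= 0))
})

test_that("edge-wise t-tests find planted effects and nothing else", {
  set.seed(3)
  n_edge <- 595
  a <- matrix(rnorm(17 * n_edge), 17)
  expect_false(any(edgewise_ttest(a, a)$selected))

  hits <- vapply(1:50, function(i) {
    base <- matrix(rnorm(17 * n_edge), 17)
    shifted <- matrix(rnorm(17 * n_edge), 17)
    shifted[, 100] <- shifted[, 100] + 5 # a 5-pooled-SD planted effect
    out <- edgewise_ttest(shifted, base)
    out$selected[100]
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  b <- matrix(rnorm(17 * n_edge, 0.1), 17)
  out <- edgewise_ttest(a, b)
  expect_equal(sum(out$selected), sum(out$p < 0.01))
  # one edge cross-checked against the reference implementation
  tt <- t.test(a[, 7], b[, 7], var.equal = TRUE)
  expect_equal(out$t[7], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(out$p[7], tt$p.value, tolerance = 1e-10)
})

test_that("the a-priori power search returns the minimal even total N", {
  n <- sample_size_rm_anova(f = 0.25, alpha = 0.05, power = 0.8, groups = 2,
                            measurements = 3, rho = 0.5, epsilon = 1)
  expect_equal(as.integer(n), 28L)
  expect_gte(rm_anova_power(28), 0.8)
  expect_lt(rm_anova_power(26), 0.8)
  # a larger effect needs fewer subjects
  expect_lt(as.integer(sample_size_rm_anova(f = 0.5)), 28L)
})

test_that("the two-sample test holds its nominal type-I error rate", {
  set.seed(4)
  n_rep <- 10000
  x <- matrix(rnorm(n_rep * 10), n_rep)
  y <- matrix(rnorm(n_rep * 10), n_rep)
  rej <- vapply(seq_len(n_rep), function(i) {
    ttest_ind(x[i, ], y[i, ])$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.04)
  expect_lt(mean(rej), 0.06)
})

test_that("BH keeps the realized false discovery rate at or below q", {
  set.seed(5)
  fdp <- vapply(1:2000, function(i) {
    p_null <- runif(10)
    p_alt <- pmin(1, abs(rnorm(10, 0, 1e-4)))
    rej <- fdr_bh(c(p_null, p_alt), q = 0.05)$reject
    if (!any(rej)) return(0)
    sum(rej[1:10]) / sum(rej)
  }, numeric(1))
  expect_lte(mean(fdp), 0.06)
})
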