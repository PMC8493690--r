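test_that("PAVA pools adjacent violators and conserves the weighted mean", {
  expect_equal(pava_isotonic_means(c(3, 1, 2), direction = "increasing"),
               c(2, 2, 2))
  expect_equal(pava_isotonic_means(c(1, 2, 3), direction = "increasing"),
               c(1, 2, 3))
  expect_equal(pava_isotonic_means(c(5, 4, 1), direction = "decreasing"),
               c(5, 4, 1))
  # property: monotone output, conserved weighted mean, random inputs
  set.seed(14)
  for (i in 1:200) {
    k <- sample(2:8, 1)
    x <- rnorm(k); w <- runif(k, 0.5, 5)
    y <- pava_isotonic_means(x, w, "increasing")
    expect_true(all(diff(y) >= -1e-12))
    expect_equal(sum(y * w), sum(x * w), tolerance = 1e-10)
    y2 <- pava_isotonic_means(x, w, "decreasing")
    expect_true(all(diff(y2) <= 1e-12))
    expect_equal(sum(y2 * w), sum(x * w), tolerance = 1e-10)
  }
})

test_that("Williams critical value reduces to Student t at k = 1", {
  expect_equal(critical_values_williams(1, 10, 0.025), qt(0.975, 10))
  expect_equal(critical_values_williams(1, Inf, 0.025), qnorm(0.975))
})

test_that("critical values are deterministic and non-decreasing in k", {
  cv <- vapply(1:4, function(k) {
    critical_values_williams(k, 20, 0.025, n = 6, n0 = 6)
  }, 1)
  expect_true(all(diff(cv) >= 0))
  expect_identical(critical_values_williams(3, 20, 0.025, n = 6, n0 = 6),
                   critical_values_williams(3, 20, 0.025, n = 6, n0 = 6))
})

test_that("constant data produce no significant dose", {
  s <- dose_series(rep(5, 4), list(rep(5, 4), rep(5, 4)))
  r1 <- williams_test(s)
  r2 <- shirley_williams_test(s)
  expect_false(any(r1$table$significant))
  expect_false(any(r2$table$significant))
})

test_that("step-down significance is coherent in dose", {
  set.seed(15)
  for (i in 1:50) {
    s <- dose_series(rnorm(5), list(rnorm(5, -0.5), rnorm(5, -1),
                                    rnorm(5, -1.5)),
                     direction = "decreasing")
    for (r in list(williams_test(s, n_mc = 20000L),
                   shirley_williams_test(s, n_mc = 20000L))) {
      sig <- r$table$significant
      # once non-significant, everything below is non-significant
      if (any(!sig)) expect_false(any(sig[seq_len(max(which(!sig)))]))
    }
  }
})

test_that("the rank trend test is invariant to monotone transforms", {
  set.seed(16)
  ctrl <- rnorm(6, 10); d1 <- rnorm(6, 9); d2 <- rnorm(6, 7)
  s <- dose_series(ctrl, list(d1, d2), direction = "decreasing")
  tr <- function(x) exp(x / 3)  # strictly increasing
  s2 <- dose_series(tr(ctrl), list(tr(d1), tr(d2)),
                    direction = "decreasing")
  r1 <- shirley_williams_test(s)
  r2 <- shirley_williams_test(s2)
  expect_identical(r1$table$significant, r2$table$significant)
  expect_equal(r1$table$statistic, r2$table$statistic)
})

test_that("heterogeneity gate follows Bartlett's test", {
  set.seed(17)
  hom <- dose_series(rnorm(6), list(rnorm(6), rnorm(6)))
  expect_equal(heterogeneity_gate(hom)$test, "williams")
  het <- dose_series(rnorm(6, sd = 1),
                     list(rnorm(6, sd = 1), rnorm(6, sd = 1),
                          rnorm(6, sd = 10)))
  expect_equal(heterogeneity_gate(het)$test, "shirley_williams")
  # identical constant data everywhere: equal-variances convention
  const <- dose_series(rep(2, 4), list(rep(2, 4)))
  expect_equal(heterogeneity_gate(const)$test, "williams")
  # one degenerate group among variable ones: fall back with a warning
  mixed <- dose_series(rnorm(6), list(rep(1, 6), rnorm(6)))
  expect_warning(g <- heterogeneity_gate(mixed), "zero-variance")
  expect_equal(g$test, "shirley_williams")
})

test_that("gate size matches the Bartlett level under the null", {
  set.seed(18)
  picks <- vapply(seq_len(3000), function(i) {
    s <- dose_series(rnorm(6), list(rnorm(6), rnorm(6), rnorm(6)))
    heterogeneity_gate(s)$test == "shirley_williams"
  }, TRUE)
  expect_lt(abs(mean(picks) - 0.05), 0.015)
})

test_that("two-group comparison matches its oracles", {
  # exhaustive rank-sum enumeration at n1 = n2 = 6: complete separation
  # has probability 2/choose(12, 6)
  r <- two_group_test(1:6, 11:16, method = "wilcoxon")
  expect_equal(r$p, 2 / choose(12, 6), tolerance = 1e-12)
  expect_true(r$significant)
  # label swap leaves the two-sided p unchanged
  set.seed(19)
  a <- rnorm(8); b <- rnorm(8, 1)
  expect_equal(two_group_test(a, b)$p, two_group_test(b, a)$p)
  # identical groups are never significant
  r0 <- two_group_test(rep(3, 5), rep(3, 5))
  expect_equal(r0$p, 1)
  expect_false(r0$significant)
  expect_error(two_group_test(1, 1:3), "at least 2")
})

test_that("williams statistic equals the two-sample t when k = 1", {
  set.seed(20)
  ctrl <- rnorm(6); trt <- rnorm(6, 1)
  s <- dose_series(ctrl, list(trt), direction = "increasing")
  r <- williams_test(s)
  tt <- t.test(trt, ctrl, var.equal = TRUE)$statistic
  expect_equal(unname(r$table$statistic), unname(tt), tolerance = 1e-10)
})
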