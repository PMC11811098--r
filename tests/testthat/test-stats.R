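test_that("Bland-Altman reproduces hand arithmetic in percent mode", {
  # identical series: zero difference and degenerate limits
  ba0 <- bland_altman(c(3, 5, 7), c(3, 5, 7))
  expect_equal(ba0$mean_diff, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))

  # pairs (10,9), (10,11): d = +100/9.5, -100/10.5
  ba <- bland_altman(c(10, 10), c(9, 11))
  d <- c(100 / 9.5, -100 / 10.5)
  expect_equal(ba$mean_diff, mean(d))
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d))
  expect_equal(round(c(ba$loa_low, ba$loa_high), 2), c(-27.29, 28.29))

  expect_error(bland_altman(10, 9), "fewer than 2")
  # zero-mean pairs are excluded in percent mode
  expect_equal(bland_altman(c(0, 10, 10), c(0, 9, 11))$n_used, 2)
})

test_that("Bland-Altman is antisymmetric in its arguments", {
  set.seed(1)
  a <- rpois(20, 6); b <- rpois(20, 6)
  for (mode in c("percent", "raw")) {
    ab <- bland_altman(a, b, mode)
    ba <- bland_altman(b, a, mode)
    expect_equal(ab$mean_diff, -ba$mean_diff)
    expect_equal(ab$loa_low, -ba$loa_high)
    expect_equal(ab$loa_high, -ba$loa_low)
  }
})

test_that("ICC matches an independently computed two-way random form", {
  expect_equal(icc_absolute(cbind(c(1, 2, 3), c(1, 2, 3))), 1.0)
  expect_error(icc_absolute(cbind(rep(2, 3), rep(2, 3))), "constant")
  # frozen oracle values (two-way random, absolute agreement, single measure)
  expect_equal(icc_absolute(cbind(c(1, 2, 3), c(3, 2, 1))), -3)
  expect_equal(icc_absolute(cbind(c(4, 6, 8), c(4.1, 6.2, 7.9))),
               0.9973753280839893)
  expect_equal(icc_absolute(cbind(c(1, 2, 3, 4, 6), c(2, 1, 4, 3, 7))),
               0.8863636363636364)
  expect_error(icc_absolute(cbind(1:2, 2:1)), "at least 3")
})

test_that("ICC is exactly 1 only for identical raters", {
  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(6)
    expect_equal(icc_absolute(cbind(x, x)), 1.0)
    expect_lt(icc_absolute(cbind(x, x + rnorm(6, 0, 0.3))), 1.0)
  }
})

test_that("Cohen's kappa reproduces hand examples and relabeling invariance", {
  expect_equal(cohen_kappa(c("a", "b", "a"), c("a", "b", "a")), 1.0)
  # 2x2 counts a=0, b=5, c=5, d=0: perfect disagreement
  x <- rep(c("p", "n"), each = 5)
  y <- rep(c("n", "p"), each = 5)
  expect_equal(cohen_kappa(x, y), -1.0)
  # all four cells equal: chance-level agreement
  x2 <- c("p", "p", "n", "n"); y2 <- c("p", "n", "p", "n")
  expect_equal(cohen_kappa(x2, y2), 0.0)
  # relabeling invariance
  relab <- c(p = "existence", n = "disappearance")
  expect_equal(cohen_kappa(relab[x], relab[y]), cohen_kappa(x, y))
  expect_error(cohen_kappa(rep("a", 4), rep("a", 4)), "degenerate")
})

test_that("Spearman correlation handles monotone and hand cases", {
  expect_equal(spearman_corr(1:5, c(2, 4, 6, 9, 20))$rho, 1)
  expect_equal(spearman_corr(1:5, -(1:5))$rho, -1)
  expect_equal(spearman_corr(1:4, c(1, 3, 2, 4))$rho, 0.8)
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
  expect_error(spearman_corr(1:2, 1:2), "at least 3")
})

test_that("group comparison screens normality and detects shifts", {
  set.seed(3)
  g <- rnorm(30)
  same <- compare_groups(g, g)
  expect_identical(same$test, "t")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # seeded shift of 2 sd at n = 50 is detected
  set.seed(4)
  g1 <- rnorm(50); g2 <- rnorm(50, 2)
  r <- compare_groups(g1, g2)
  expect_lt(r$p, 0.05)

  # clearly non-normal data fall back to Mann-Whitney
  set.seed(5)
  e1 <- rexp(40)^2; e2 <- rexp(40)^2 + 1
  expect_identical(compare_groups(e1, e2)$test, "mann-whitney")

  expect_error(compare_groups(c(1, 2), rnorm(10)), "at least 3")
})
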