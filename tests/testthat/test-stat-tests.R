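test_that("Welch t matches the closed form on a fixed toy", {
  x <- c(10, 12, 14); y <- c(5, 6, 7)
  r <- welch_t(x, y)
  # by hand: means 12 and 6, variances 4 and 1
  se2 <- 4 / 3 + 1 / 3
  expect_equal(r$statistic, 6 / sqrt(se2), tolerance = 1e-12)
  expect_equal(r$df, se2^2 / ((4 / 3)^2 / 2 + (1 / 3)^2 / 2), tolerance = 1e-12)
  expect_equal(r$p, 2 * stats::pt(-abs(r$statistic), r$df), tolerance = 1e-12)
  # identical samples: t = 0, p = 1; swapping groups negates t
  same <- welch_t(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_equal(welch_t(y, x)$statistic, -r$statistic)
  expect_equal(welch_t(y, x)$p, r$p)
  expect_error(welch_t(c(1, 1), c(1, 1)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), ">= 2")
})

test_that("Welch t agrees with t.test on random instances to 1e-8", {
  set.seed(101)
  for (i in 1:100) {
    x <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:20, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    got <- welch_t(x, y)
    want <- stats::t.test(x, y)
    expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-8)
    expect_equal(got$df, unname(want$parameter), tolerance = 1e-8)
    expect_equal(got$p, want$p.value, tolerance = 1e-8)
  }
})

test_that("chi-square GOF agrees with chisq.test and validates input", {
  flat <- chi2_gof(c(500, 500), c(500, 500))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  set.seed(103)
  for (i in 1:100) {
    k <- sample(2:6, 1)
    obs <- rpois(k, lambda = sample(5:200, 1))
    if (sum(obs) == 0) next
    got <- chi2_gof(obs)
    want <- suppressWarnings(stats::chisq.test(obs))
    expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-8)
    expect_equal(got$p, want$p.value, tolerance = 1e-8)
  }
  expect_error(chi2_gof(c(1, 2), c(1, 0)), "positive")
  expect_error(chi2_gof(c(1, 2), c(1, 2, 3)), "mismatch")
})

test_that("BH adjustment reproduces the step-up formula and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)), c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(107)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    got <- bh_adjust(p)
    expect_equal(got, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(got >= p - 1e-12))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), got[perm])
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("one-way ANOVA matches aov on random instances", {
  set.seed(109)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(3:12, 1), mean = j / 2))
    got <- anova_one_way(groups)
    df <- data.frame(y = unlist(groups),
                     g = factor(rep(seq_len(k), lengths(groups))))
    want <- summary(stats::aov(y ~ g, df))[[1]]
    expect_equal(got$statistic, want[["F value"]][1], tolerance = 1e-8)
    expect_equal(got$p, want[["Pr(>F)"]][1], tolerance = 1e-8)
    expect_equal(got$df, c(k - 1, nrow(df) - k))
  }
})

test_that("balanced two-way ANOVA matches hand computation and aov", {
  # balanced 2x2 toy with r = 2 and known cell means
  y <- c(10, 12, 20, 22, 30, 32, 44, 46)
  a <- rep(c("a1", "a2"), each = 4)
  b <- rep(rep(c("b1", "b2"), each = 2), 2)
  got <- anova_two_way(y, a, b)
  want <- summary(stats::aov(y ~ A * B, data.frame(y = y, A = a, B = b)))[[1]]
  expect_equal(got$factor_a$statistic, want[["F value"]][1], tolerance = 1e-8)
  expect_equal(got$factor_b$statistic, want[["F value"]][2], tolerance = 1e-8)
  expect_equal(got$interaction$statistic, want[["F value"]][3], tolerance = 1e-8)
  expect_equal(got$factor_a$p, want[["Pr(>F)"]][1], tolerance = 1e-8)
  # identical cell means: zero F for both factors
  flat <- anova_two_way(rep(c(1, 3), 4), a, b)
  expect_equal(flat$factor_a$statistic, 0)
  expect_equal(flat$factor_b$statistic, 0)
  expect_error(anova_two_way(y[1:7], a[1:7], b[1:7]), "unbalanced")
})

test_that("balanced two-way ANOVA agrees with aov on random instances", {
  set.seed(113)
  for (i in 1:25) {
    a_lev <- sample(2:4, 1); b_lev <- sample(2:3, 1); r <- sample(2:4, 1)
    grid <- expand.grid(A = paste0("a", 1:a_lev), B = paste0("b", 1:b_lev),
                        rep = 1:r)
    grid$y <- rnorm(nrow(grid)) + as.integer(grid$A) + 0.5 * as.integer(grid$B)
    got <- anova_two_way(grid$y, grid$A, grid$B)
    want <- summary(stats::aov(y ~ A * B, grid))[[1]]
    expect_equal(got$factor_a$statistic, want[["F value"]][1], tolerance = 1e-8)
    expect_equal(got$factor_b$statistic, want[["F value"]][2], tolerance = 1e-8)
    expect_equal(got$interaction$statistic, want[["F value"]][3], tolerance = 1e-8)
    expect_equal(got$factor_a$p, want[["Pr(>F)"]][1], tolerance = 1e-8)
    expect_equal(got$factor_b$p, want[["Pr(>F)"]][2], tolerance = 1e-8)
  }
})

test_that("rank-based wrappers agree with the reference implementations", {
  set.seed(127)
  groups <- list(rnorm(8), rnorm(10, 1), rnorm(6, 2))
  got <- kruskal_wallis(groups)
  want <- stats::kruskal.test(groups)
  expect_equal(got$statistic, unname(want$statistic), tolerance = 1e-12)
  expect_equal(got$p, want$p.value, tolerance = 1e-12)
  dn <- dunn_test(setNames(groups, c("a", "b", "c")))
  expect_equal(nrow(dn), 3)
  expect_true(all(dn$p_adj >= dn$p))
  # the most separated pair has the largest |z|
  expect_equal(which.max(abs(dn$z)), which(dn$group1 == "a" & dn$group2 == "c"))
})
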