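test_that("spearman_test hits the exact extremes and matches rank-then-Pearson", {
  expect_equal(spearman_test(1:10, 1:10)$statistic, 1)
  expect_equal(spearman_test(1:10, 10:1)$statistic, -1)
  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    if (runif(1) < 0.5) y[1:2] <- y[3:4] # inject ties sometimes
    got <- spearman_test(x, y)
    expect_equal(got$statistic, stats::cor(rank(x), rank(y)), tolerance = 1e-12)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    expect_equal(got$statistic, unname(ref$estimate), tolerance = 1e-12)
  }
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(3)
  x <- rnorm(25); y <- rnorm(25)
  base <- spearman_test(x, y)$statistic
  expect_equal(spearman_test(exp(x), y)$statistic, base)
  expect_equal(spearman_test(x, y^3 + 5 * y)$statistic, base)
})

test_that("degenerate ranks yield a not-computable result, not an error", {
  out <- spearman_test(rep(1, 5), 1:5)
  expect_true(is.na(out$statistic))
  expect_match(out$note, "not computable")
})

test_that("exact permutation p-value is available for tiny samples", {
  # for y = x on n = 5, only the identity and full reversal reach |rho| = 1,
  # so the two-sided exact p is 2/5! = 1/60
  out <- spearman_test(1:5, 1:5, exact = TRUE)
  expect_equal(out$p_value, 1 / 60)
  expect_error(spearman_test(1:9, 9:1, exact = TRUE),
               class = "riskspectra_domain_error")
})

test_that("chi-square tests match direct evaluation and the z^2 identity", {
  at_expectation <- chi2_gof(c(50, 50), c(0.5, 0.5))
  expect_equal(at_expectation$statistic, 0)
  expect_equal(at_expectation$p_value, 1)

  tab <- rbind(c(10, 90), c(20, 80))
  got <- chi2_2x2(tab)
  # hand evaluation: E = (15,85,15,85); sum((O-E)^2/E) = 2*(25/15) + 2*(25/85)
  expect_equal(got$statistic, 2 * 25 / 15 + 2 * 25 / 85, tolerance = 1e-12)
  ref <- stats::chisq.test(tab, correct = FALSE)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)

  # 1-df chi-square equals the squared two-proportion z statistic
  n1 <- 100; n2 <- 100; x1 <- 10; x2 <- 20
  pp <- (x1 + x2) / (n1 + n2)
  z <- (x1 / n1 - x2 / n2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  expect_equal(got$statistic, z^2, tolerance = 1e-12)
})

test_that("chi-square gof is invariant to the scale of the expected weights", {
  obs <- c(12, 30, 58)
  a <- chi2_gof(obs, c(0.1, 0.3, 0.6))
  b <- chi2_gof(obs, c(1, 3, 6))
  expect_equal(a$statistic, b$statistic)
  expect_gte(a$statistic, 0)
  expect_error(chi2_gof(obs, c(0, 0.4, 0.6)), class = "riskspectra_domain_error")
})

test_that("2x2 chi-square flags tiny expected cells instead of failing", {
  out <- chi2_2x2(rbind(c(1, 200), c(0, 150)))
  expect_match(out$note, "expected cell")
})

test_that("anova_binary reproduces explicit sums of squares and the F = t^2 identity", {
  flat <- anova_binary(rep(c(1, 0), 10), rep(1:2, each = 10))
  expect_equal(flat$statistic, 0)

  # two groups (1,1,0,0) vs (1,0,0,0): SSB = 1/8, SSW = 7/4, F = 3/7
  got <- anova_binary(c(1, 1, 0, 0, 1, 0, 0, 0), rep(c("a", "b"), each = 4))
  expect_equal(got$statistic, 3 / 7, tolerance = 1e-12)
  expect_equal(unname(got$df), c(1, 6))

  set.seed(8)
  ind <- rbinom(60, 1, 0.5)
  grp <- rep(c("x", "y"), each = 30)
  f <- anova_binary(ind, grp)
  tt <- stats::t.test(ind[grp == "x"], ind[grp == "y"], var.equal = TRUE)
  expect_equal(f$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(f$p_value, tt$p.value, tolerance = 1e-10)

  # independent route: stats::aov on fuzzed multi-group data
  for (i in 1:10) {
    k <- sample(3:6, 1)
    g <- rep(seq_len(k), times = sample(5:15, k, TRUE))
    x <- rbinom(length(g), 1, runif(1, 0.2, 0.8))
    if (var(x) == 0) next
    mine <- anova_binary(x, g)
    ref <- stats::anova(stats::aov(x ~ factor(g)))
    expect_equal(mine$statistic, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(mine$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
  }

  expect_error(anova_binary(c(0, 1, 1), c("a", "b", "c")),
               class = "riskspectra_domain_error")
})

test_that("rs_test objects tidy into one-row tibbles", {
  td <- tidy(spearman_test(1:8, c(2, 1, 4, 3, 6, 5, 8, 7)))
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_named(td, c("method", "statistic", "df1", "df2", "p_value", "n", "note"))
  gl <- glance(chi2_gof(c(5, 5), c(0.5, 0.5)))
  expect_equal(gl$df1, 1)
})
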