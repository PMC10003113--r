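# The statistical ladder: effect sizes, flags, normality gate, test
# routing, Dunnett cross-check, and the report round trip.

test_that("percent change reproduces the published worked examples", {
  expect_equal(percent_change(259.69, 454.06)$rounded, -43)
  expect_equal(percent_change(81.56, 52.1)$rounded, 57)
  expect_equal(percent_change(5, 5)$rounded, 0)
  expect_error(percent_change(1, 0), "non-zero")
  # half away from zero
  expect_equal(percent_change(1255, 1000)$rounded, 26)
  expect_equal(percent_change(745, 1000)$rounded, -26)
})

test_that("percent change is antisymmetric under swapping roles", {
  set.seed(8)
  for (i in 1:20) {
    a <- runif(1, 1, 100); b <- runif(1, 1, 100)
    p <- percent_change(a, b)$raw
    q <- percent_change(b, a)$raw
    expect_equal(q, -100 * p / (100 + p), tolerance = 1e-9)
  }
})

test_that("significance flags use the most significant applicable threshold", {
  expect_equal(significance_flag(0.03), "*")
  expect_equal(significance_flag(0.0005), "***")
  expect_equal(significance_flag(0.005), "**")
  expect_equal(significance_flag(0.07), "#")
  expect_equal(significance_flag(0.5), "ns")
  expect_error(significance_flag(1.2), "0, 1")
  # monotone: smaller p never gets a less significant flag
  order_of <- c(ns = 0, `#` = 1, `*` = 2, `**` = 3, `***` = 4)
  ps <- sort(runif(50))
  fl <- order_of[vapply(ps, significance_flag, character(1))]
  expect_true(all(diff(fl) <= 0))
})

test_that("normality gate routes by Shapiro-Wilk on every group", {
  set.seed(3)
  norm3 <- replicate(3, rnorm(50), simplify = FALSE)
  expect_equal(normality_gate(norm3), "parametric")
  skew <- replicate(3, exp(rnorm(50)), simplify = FALSE)
  expect_equal(normality_gate(skew), "nonparametric")
  expect_error(normality_gate(list(rnorm(50), rep(1, 10))), "degenerate")
  expect_error(normality_gate(list(rnorm(50), rnorm(2))), "n >= 3")
})

test_that("gate calibration matches the triple-testing level", {
  set.seed(11)
  par_rate <- mean(vapply(1:400, function(i)
    normality_gate(replicate(3, rnorm(50), simplify = FALSE)) ==
      "parametric", logical(1)))
  expect_lt(abs(par_rate - 0.95^3), 0.05)
  skew_rate <- mean(vapply(1:100, function(i)
    normality_gate(replicate(3, exp(rnorm(50)), simplify = FALSE)) ==
      "nonparametric", logical(1)))
  expect_gte(skew_rate, 0.99)
})

test_that("routing contract: two groups never get an ANOVA", {
  set.seed(4)
  v <- c(rnorm(12), rnorm(12, 1))
  g <- rep(c("ctrl", "trt"), each = 12)
  cmp <- compare_groups(v, g, reference = "ctrl", gate = "parametric")
  expect_equal(cmp$test, "unpaired t-test")
  cmp2 <- compare_groups(v, g, reference = "ctrl", gate = "nonparametric")
  expect_equal(cmp2$test, "Mann-Whitney U")
  v3 <- c(v, rnorm(12, 2)); g3 <- c(g, rep("trt2", 12))
  cmp3 <- compare_groups(v3, g3, reference = "ctrl", gate = "parametric")
  expect_equal(unique(cmp3$test), "one-way ANOVA + Dunnett")
  cmp4 <- compare_groups(v3, g3, reference = "ctrl", gate = "nonparametric")
  expect_equal(unique(cmp4$test), "Kruskal-Wallis + Mann-Whitney U")
  expect_error(compare_groups(v, g, reference = "nope"), "reference")
})

test_that("paired designs route to the signed-rank test", {
  set.seed(6)
  v <- c(rnorm(10), rnorm(10, 0.5))
  g <- rep(c("before", "after"), each = 10)
  cmp <- compare_groups(v, g, reference = "before", design = "paired",
                        gate = "nonparametric")
  expect_equal(cmp$test, "Wilcoxon signed-rank")
})

test_that("a 3-SD shift is flagged *** against the control", {
  hits <- 0L
  for (s in 1:50) {
    set.seed(1000 + s)
    v <- c(rnorm(30), rnorm(30), rnorm(30, 3))
    g <- rep(c("ctrl", "a", "b"), each = 30)
    cmp <- compare_groups(v, g, reference = "ctrl", gate = "parametric")
    hits <- hits + (cmp$flag[cmp$group == "b"] == "***")
  }
  expect_gte(hits / 50, 0.95)
})

test_that("Monte-Carlo Dunnett agrees with the multcomp implementation", {
  skip_if_not_installed("multcomp")
  set.seed(9)
  d <- data.frame(y = c(rnorm(15), rnorm(15, 0.8), rnorm(15, 0.3)),
                  g = factor(rep(c("ctrl", "a", "b"), each = 15),
                             levels = c("ctrl", "a", "b")))
  ours <- dunnett_test(split(d$y, d$g)[c("ctrl", "a", "b")], "ctrl")
  fit <- multcomp::glht(stats::aov(y ~ g, data = d),
                        linfct = multcomp::mcp(g = "Dunnett"))
  ref <- summary(fit)$test
  expect_equal(ours$p[match(c("a", "b"), ours$group)],
               as.numeric(ref$pvalues), tolerance = 0.01)
  expect_equal(ours$statistic[match(c("a", "b"), ours$group)],
               as.numeric(ref$tstat), tolerance = 1e-8)
})

test_that("report rendering composes annotations and round-trips exactly", {
  means <- data.frame(
    metric = rep(c("network_total_length", "avg_tree_length"), each = 2),
    condition = rep(c("untreated", "blue light"), 2),
    value = c(454.06, 259.69, 8.79, 2.79))
  cmps <- data.frame(metric = c("network_total_length", "avg_tree_length"),
                     group = "blue light", reference = "untreated",
                     effect_pct_rounded = c(-43, -68),
                     flag = c("***", "***"))
  rep1 <- render_report(means, cmps, reference = "untreated")
  expect_true(any(grepl("-43% \\*\\*\\* vs untreated",
                        rep1[["blue light"]])))
  parsed <- parse_report(rep1)
  expect_equal(parsed$value[parsed$condition == "untreated"],
               c(454.06, 8.79))
  expect_equal(parsed$value[parsed$condition == "blue light"],
               c(259.69, 2.79))
  expect_equal(parsed$effect_pct_rounded[parsed$condition == "blue light"],
               c(-43, -68))
  # values-only table when no comparisons are supplied
  rep2 <- render_report(means, NULL, reference = "untreated")
  expect_false(any(grepl("vs", rep2[["blue light"]])))
  expect_error(render_report(means, cmps, reference = "missing"),
               "reference")
})
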