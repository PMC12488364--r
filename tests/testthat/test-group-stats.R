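test_that("group summaries reproduce printed descriptive statistics", {
  # Published control log-CgA: mean 1.29, SD 0.48, n 143 -> CI [1.21, 1.37]
  set.seed(1)
  s <- summarize_group(exact_moments(143, 1.29, 0.48), group = "control")
  expect_equal(round(s$ci_low, 2), 1.21)
  expect_equal(round(s$ci_high, 2), 1.37)

  s2 <- summarize_group(exact_moments(4, 0, 1))
  expect_equal(s2$ci_low, -1.959964 / 2, tolerance = 1e-6)
  expect_equal(s2$ci_high, 1.959964 / 2, tolerance = 1e-6)

  s3 <- summarize_group(rep(2.5, 10))
  expect_equal(s3$ci_low, 2.5)
  expect_equal(s3$ci_high, 2.5)
  expect_error(summarize_group(1), "at least 2")
})

test_that("CI width shrinks at the root-n rate", {
  set.seed(2)
  widths <- vapply(c(1e2, 1e4, 1e6), function(n) {
    s <- summarize_group(exact_moments(n, 0, 1))
    s$ci_high - s$ci_low
  }, numeric(1))
  expect_equal(widths[1] / widths[2], 10, tolerance = 1e-6)
  expect_equal(widths[2] / widths[3], 10, tolerance = 1e-6)
})

test_that("LS means equal raw group means on balanced designs", {
  set.seed(3)
  dat <- expand.grid(g = c("PD", "SD"), t = c("SSA", "surgery", "other"),
                     rep = 1:10)
  dat$y <- rnorm(nrow(dat)) + (dat$g == "PD") * 0.4
  res <- ls_means_anova(dat$y, dat$g, dat$t)
  raw <- tapply(dat$y, dat$g, mean)
  expect_equal(res$ls_means$lsmean,
               as.numeric(raw[res$ls_means$group]), tolerance = 1e-12)
})

test_that("single treatment level reduces to classic one-way ANOVA", {
  set.seed(4)
  y <- rnorm(40); g <- rep(c("PD", "SD"), each = 20)
  res <- ls_means_anova(y, g, rep("SSA", 40))
  m <- tapply(y, g, mean); n <- c(20, 20)
  ssb <- sum(n * (m - mean(y))^2)
  ssw <- sum((y - m[g])^2)
  f_closed <- (ssb / 1) / (ssw / 38)
  expect_equal(res$f_statistic, f_closed, tolerance = 1e-12)
  expect_equal(res$df, c(1, 38))
})

test_that("LS means and group test agree with emmeans on unbalanced data", {
  set.seed(5)
  n <- 90
  g <- sample(c("PD", "SD"), n, TRUE, prob = c(0.6, 0.4))
  t <- sample(c("SSA", "surgery", "other"), n, TRUE, prob = c(0.5, 0.3, 0.2))
  y <- rnorm(n) + 0.5 * (g == "PD") + 0.3 * (t == "surgery")
  res <- ls_means_anova(y, g, t)
  fit <- stats::lm(y ~ g + t, data = data.frame(y, g = factor(g), t = factor(t)))
  em <- as.data.frame(emmeans::emmeans(fit, "g"))
  expect_equal(res$ls_means$lsmean, em$emmean, tolerance = 1e-10)
  expect_equal(res$ls_means$se, em$SE, tolerance = 1e-10)
})

test_that("aliased designs raise an informative error", {
  y <- rnorm(20)
  g <- rep(c("PD", "SD"), each = 10)
  expect_error(ls_means_anova(y, g, g), "aliased")
})

test_that("group p-values are uniform under the null", {
  set.seed(6)
  pvals <- vapply(1:800, function(i) {
    g <- sample(c("PD", "SD"), 60, TRUE)
    t <- sample(c("a", "b", "c"), 60, TRUE)
    ls_means_anova(rnorm(60), g, t)$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("logistic LRT equals the G-test on a 2x2 table", {
  outcome <- c(rep("PD", 30), rep("SD", 25), rep("PD", 10), rep("SD", 20))
  arm <- c(rep("SSA", 55), rep("other", 30))
  res <- logistic_group_test(outcome, arm)
  tab <- table(arm, outcome)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  g_stat <- 2 * sum(tab * log(tab / exp_tab))
  expect_equal(res$statistic, g_stat, tolerance = 1e-8)
  expect_equal(res$df, 1)
})

test_that("degenerate and separated logistic inputs warn but report", {
  expect_warning(res <- logistic_group_test(rep("PD", 20),
                                            rep(c("a", "b"), 10)),
                 "degenerate")
  expect_equal(res$p_value, 1, tolerance = 1e-6)
  expect_warning(res2 <- logistic_group_test(c(rep("PD", 10), rep("SD", 10)),
                                             c(rep("a", 10), rep("b", 10))),
                 "separation")
  expect_true(is.finite(res2$p_value))
})

test_that("ROC AUC matches exhaustive pair counting and pROC", {
  expect_equal(roc_auc(c(1, 2, 10, 11), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(3, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(roc_auc(1:4, c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(1:4, c(0, 1, 0, 1)), 0.75)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")

  set.seed(7)
  x <- rnorm(80); lab <- rbinom(80, 1, 0.4)
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(x, lab), roc_auc(exp(x), lab))
  ref <- as.numeric(pROC::auc(pROC::roc(lab, x, direction = "<",
                                        quiet = TRUE)))
  expect_equal(roc_auc(x, lab), ref, tolerance = 1e-12)
})

test_that("LS-mean group difference recovers the simulated CPE effect", {
  # PD ~ N(3.32, 0.74), n 65; SD ~ N(2.96, 0.33), n 50 (published group
  # parameters); treatment assigned independently of group.
  set.seed(8)
  diffs <- vapply(1:600, function(i) {
    y <- c(rnorm(65, 3.32, 0.74), rnorm(50, 2.96, 0.33))
    g <- c(rep("PD", 65), rep("SD", 50))
    t <- sample(c("SSA", "surgery", "other"), 115, TRUE)
    lsm <- ls_means_anova(y, g, t)$ls_means
    lsm$lsmean[lsm$group == "PD"] - lsm$lsmean[lsm$group == "SD"]
  }, numeric(1))
  expect_lt(abs(mean(diffs) - 0.36), 0.02)
})
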