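test_that("confusion counting is exact, total and order-invariant", {
  p <- rep("positive", 10)
  t10 <- c(rep("positive", 3), rep("negative", 7))
  cm <- confusion_from_predictions(p, t10)
  expect_equal(unclass(cm)[c("tp", "fp", "fn", "tn")],
               list(tp = 3, fp = 7, fn = 0, tn = 0))
  agree <- confusion_from_predictions(t10, t10)
  expect_equal(agree$fp + agree$fn, 0)
  set.seed(2)
  perm <- sample(10)
  cm2 <- confusion_from_predictions(p[perm], t10[perm])
  expect_equal(unclass(cm)[1:4], unclass(cm2)[1:4])
  expect_error(confusion_from_predictions(p[1:3], t10), "same length")
})

test_that("screening metrics reproduce the printed worked example", {
  m <- metrics_from_confusion(binary_confusion(tp = 16, fp = 10,
                                               fn = 1, tn = 19))
  expect_equal(m[["sensitivity"]], 16 / 17)
  expect_equal(round(m[["sensitivity"]], 2), 0.94)
  expect_equal(m[["npv"]], 19 / 20)
  expect_equal(m[["accuracy"]], 35 / 46)
  expect_equal(round(m[["accuracy"]], 2), 0.76)
  expect_equal(m[["ppv"]], 16 / 26)
  expect_equal(round(100 * m[["ppv"]]), 62)

  perfect <- metrics_from_confusion(binary_confusion(5, 0, 0, 7))
  expect_true(all(unclass(perfect) == 1))

  nopos <- metrics_from_confusion(binary_confusion(0, 0, 0, 4))
  expect_true(is.na(nopos[["sensitivity"]]))
  expect_identical(attr(nopos, "undefined"), c("sensitivity", "ppv"))
  expect_equal(nopos[["specificity"]], 1)
})

test_that("the random-classifier baseline reproduces chance metrics", {
  cc <- chance_confusion(chance_model(p = c(17 / 46, 29 / 46)))
  expect_equal(cc$metrics[["accuracy"]], 0.5)
  expect_equal(cc$metrics[["sensitivity"]], 0.5)
  expect_equal(cc$metrics[["npv"]], 29 / 46)
  expect_equal(round(100 * cc$metrics[["npv"]]), 63)
  expect_equal(sum(cc$cells), 1)

  k4 <- chance_confusion(chance_model(q = rep(0.25, 4), p = rep(0.25, 4)))
  expect_equal(k4$accuracy, 0.25)

  expect_error(chance_model(q = c(0.5, 0.4), p = c(0.5, 0.5)), "sum to 1")
})

test_that("chance NPV equals the negative-class prior for any selection q", {
  set.seed(8)
  for (i in 1:50) {
    qpos <- runif(1, 0.05, 0.95)
    ppos <- runif(1, 0.05, 0.95)
    cc <- chance_confusion(chance_model(q = c(qpos, 1 - qpos),
                                        p = c(ppos, 1 - ppos)))
    expect_equal(cc$metrics[["npv"]], 1 - ppos, tolerance = 1e-12)
    expect_equal(cc$metrics[["sensitivity"]], qpos, tolerance = 1e-12)
  }
})

test_that("ROC handles the canonical small cases", {
  r1 <- roc_curve(c(5, 6, 7, 8), c("impaired", "impaired",
                                   "intact", "intact"))
  expect_equal(roc_auc(r1), 1.0)
  r2 <- roc_curve(c(6, 8, 7, 8), c("impaired", "impaired",
                                   "intact", "intact"))
  expect_equal(roc_auc(r2), 0.625)
  r3 <- roc_curve(c(4, 4, 4, 4), c("impaired", "impaired",
                                   "intact", "intact"))
  expect_equal(roc_auc(r3), 0.5)
  expect_error(roc_curve(1:3, rep("impaired", 3)), "one positive and one")
  # curve shape: monotone sweep from strictest to loosest
  expect_true(all(diff(r2$sensitivity) >= 0))
  expect_true(all(diff(r2$fpr) >= 0))
  expect_equal(r2$sensitivity[nrow(r2)], 1)
  expect_equal(r2$fpr[nrow(r2)], 1)
})

test_that("trapezoidal AUC equals Mann-Whitney concordance exactly", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    npos <- sample(seq_len(n - 1), 1)
    truth <- c(rep("impaired", npos), rep("intact", n - npos))
    scores <- sample(0:8, n, replace = TRUE)
    expect_equal(roc_auc(roc_curve(scores, truth)),
                 mw_concordance(scores, truth), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  for (i in 1:10) {
    status <- c(rep(1, 8), rep(0, 12))
    scores <- c(sample(0:7, 8, TRUE), sample(3:8, 12, TRUE))
    ours <- roc_auc(roc_curve(scores, ifelse(status == 1, "impaired",
                                             "intact")))
    ref <- suppressMessages(as.numeric(
      pROC::auc(pROC::roc(status, scores, direction = ">"))))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("Youden threshold matches brute-force J maximization", {
  r2 <- roc_curve(c(6, 8, 7, 8), c("impaired", "impaired",
                                   "intact", "intact"))
  expect_equal(youden_threshold(r2)$threshold, 6)
  expect_equal(youden_threshold(r2)$j, 0.5)
  r1 <- roc_curve(c(5, 6, 7, 8), c("impaired", "impaired",
                                   "intact", "intact"))
  expect_equal(youden_threshold(r1)$j, 1)
  flat <- roc_curve(c(4, 4, 4, 4), c("impaired", "impaired",
                                     "intact", "intact"))
  expect_equal(youden_threshold(flat)$threshold, -Inf)  # strictest on ties
  set.seed(21)
  for (i in 1:50) {
    n <- sample(5:14, 1)
    npos <- sample(seq_len(n - 1), 1)
    truth <- c(rep("impaired", npos), rep("intact", n - npos))
    scores <- sample(0:8, n, replace = TRUE)
    roc <- roc_curve(scores, truth)
    got <- youden_threshold(roc)
    brute <- max(roc$sensitivity + roc$specificity - 1)
    expect_equal(got$j, brute, tolerance = 1e-12)
    expect_equal(got$threshold,
                 roc$threshold[which(roc$youden_j >= brute - 1e-12)[1]])
  }
})

test_that("bootstrap intervals are seed-stable and collapse on constants", {
  const <- rep(3.5, 20)
  b <- bootstrap_statistic(const, mean, n_boot = 100, seed = 1)
  expect_equal(b$ci_low, 3.5)
  expect_equal(b$ci_high, 3.5)
  set.seed(2)
  x <- rnorm(50)
  b1 <- bootstrap_statistic(x, mean, n_boot = 500, seed = 9)
  b2 <- bootstrap_statistic(x, mean, n_boot = 500, seed = 9)
  expect_identical(b1$values, b2$values)
  expect_identical(c(b1$ci_low, b1$ci_high), c(b2$ci_low, b2$ci_high))
  expect_error(bootstrap_statistic(1, mean), "at least 2")
})

test_that("undefined resamples are redrawn and counted", {
  dat <- data.frame(status = c("impaired", rep("intact", 9)),
                    score = c(2, rep(8, 9)))
  stat <- function(d) roc_auc(roc_curve(d$score, d$status))
  b <- bootstrap_statistic(dat, stat, n_boot = 50, seed = 4)
  expect_gt(b$n_redrawn, 0)               # some resamples miss the impaired
  expect_true(all(is.finite(b$values)))
})

test_that("percentile intervals attain near-nominal coverage", {
  set.seed(60)
  n_outer <- 500
  covered <- logical(n_outer)
  for (i in seq_len(n_outer)) {
    x <- rnorm(200, mean = 1.3, sd = 1)
    b <- bootstrap_statistic(x, mean, n_boot = 1000)
    covered[i] <- b$ci_low <= 1.3 && 1.3 <= b$ci_high
  }
  expect_lt(abs(mean(covered) - 0.95), 0.03)
})

test_that("chance-level p-values follow the counting rule with its floor", {
  x <- rep(1, 30)
  p0 <- p_vs_chance(x, mean, chance_value = 0.5, n_boot = 200, seed = 3)
  expect_equal(p0$count, 0)
  expect_true(p0$below_floor)
  expect_equal(p0$p_floor, 1 / 200)
  expect_match(p0$label, "<")
  # statistic identically equal to chance: p = 1 under the <= rule
  p1 <- p_vs_chance(x, mean, chance_value = 1, n_boot = 200, seed = 3)
  expect_equal(p1$p, 1)
  # strongly separated simulated cohort: AUC never at or below 0.5
  cohort <- simulate_cohort(degenerate_cohort_spec(46), seed = 5)
  pa <- p_vs_chance(cohort[, c("score", "status")],
                    function(d) roc_auc(roc_curve(d$score, d$status)),
                    chance_value = 0.5, n_boot = 1000, seed = 6)
  expect_equal(pa$count, 0)
  expect_true(pa$below_floor)
})

test_that("threshold sweep equals per-threshold brute force", {
  cohort <- simulate_cohort(cohort_spec(n = 120), seed = 31)
  sw <- threshold_sweep(cohort, n_boot = 100, seed = 32)
  for (t in 0:8) {
    dec <- ifelse(cohort$score <= t, "impaired", "intact")
    cm <- confusion_from_predictions(dec, cohort$status,
                                     positive = "impaired")
    want <- metrics_from_confusion(cm)
    rows <- sw[sw$threshold == t, ]
    for (metric in names(want)) {
      got <- rows$estimate[rows$metric == metric]
      if (is.na(want[[metric]])) expect_true(is.na(got))
      else expect_equal(got, want[[metric]], tolerance = 1e-12)
    }
  }
  loosest <- sw[sw$threshold == 8, ]
  expect_equal(loosest$estimate[loosest$metric == "sensitivity"], 1)
  expect_equal(loosest$estimate[loosest$metric == "specificity"], 0)
})

test_that("a perfectly separating cohort maximizes sensitivity and NPV", {
  cohort <- simulate_cohort(degenerate_cohort_spec(60), seed = 41)
  sw <- threshold_sweep(cohort, n_boot = 100, seed = 42)
  best <- attr(sw, "best")
  expect_equal(best$sensitivity, 1)
  expect_equal(best$npv, 1)
  expect_lt(best$threshold, 8)
})

test_that("Hanley-McNeil variance components evaluate correctly", {
  expect_equal(hanley_mcneil_variance(0.5, 1, 1), 0.25)
  q <- hanley_mcneil_q(0.7)
  expect_equal(q$q1, 0.7 / 1.3)
  expect_equal(q$q2, 0.98 / 1.7)
  ns <- vapply(seq(0.6, 0.95, by = 0.05), function(a) {
    hanley_mcneil_n(a)$n_per_group
  }, numeric(1))
  expect_true(all(diff(ns) <= 0))
  expect_error(hanley_mcneil_n(0.5), "strictly between")
  expect_error(hanley_mcneil_n(0.4), "strictly between")
  res <- hanley_mcneil_n(0.7, alpha = 0.05, power = 0.8, sided = 1)
  # the returned n is the smallest satisfying the power inequality
  crit <- function(n) {
    (0.7 - 0.5) - res$z_alpha * sqrt(hanley_mcneil_variance(0.5, n, n)) -
      res$z_power * sqrt(hanley_mcneil_variance(0.7, n, n))
  }
  expect_gte(crit(res$n_per_group), 0)
  expect_lt(crit(res$n_per_group - 1), 0)
})
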