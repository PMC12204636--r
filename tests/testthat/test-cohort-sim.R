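test_that("degenerate failure probabilities separate the cohort perfectly", {
  cohort <- simulate_cohort(degenerate_cohort_spec(200), seed = 1)
  expect_true(all(cohort$score[cohort$status == "intact"] == 8))
  expect_true(all(cohort$score[cohort$status == "impaired"] == 0))
  expect_equal(roc_auc(roc_curve(cohort$score, cohort$status)), 1.0)
})

test_that("impairment prevalence concentrates at its binomial rate", {
  cohort <- simulate_cohort(cohort_spec(n = 2000, prevalence = 0.37),
                            seed = 2)
  frac <- mean(cohort$status == "impaired")
  expect_lt(abs(frac - 0.37), 3 * sqrt(0.37 * 0.63 / 2000))
})

test_that("cohort simulation is seed-deterministic", {
  spec <- cohort_spec(n = 80)
  expect_identical(simulate_cohort(spec, seed = 3),
                   simulate_cohort(spec, seed = 3))
  expect_false(identical(simulate_cohort(spec, seed = 3),
                         simulate_cohort(spec, seed = 4)))
})

test_that("scores are rubric-consistent and live on the reachable support", {
  cohort <- simulate_cohort(cohort_spec(n = 400), seed = 5)
  recomputed <- vapply(seq_len(nrow(cohort)), function(i) {
    score_battery(c(cube = cohort$cube[i], infinity = cohort$infinity[i],
                    clock = cohort$clock[i]))
  }, integer(1))
  expect_identical(cohort$score, recomputed)
  expect_true(all(cohort$score %in% score_support()))
  expect_false(any(cohort$score == 4))
})

test_that("closed-form enumeration handles degenerate and null specs", {
  perf <- closed_form_performance(degenerate_cohort_spec())
  expect_equal(perf$metrics[["sensitivity"]], 1)
  expect_equal(perf$metrics[["specificity"]], 1)
  expect_equal(perf$auc, 1)
  null_spec <- cohort_spec(p_incorrect = matrix(
    c(0.3, 0.4, 0.5, 0.3, 0.4, 0.5), nrow = 2, byrow = TRUE,
    dimnames = list(c("intact", "impaired"),
                    c("cube", "infinity", "clock"))))
  null_perf <- closed_form_performance(null_spec)
  expect_equal(null_perf$auc, 0.5)
  # equal score distributions: every cut flags the same fraction of both
  expect_equal(null_perf$metrics[["sensitivity"]],
               1 - null_perf$metrics[["specificity"]])
  # score pmf is a distribution per status
  expect_equal(colSums(null_perf$score_pmf), c(intact = 1, impaired = 1))
})

test_that("Monte-Carlo cohorts converge to the closed-form oracle", {
  spec <- cohort_spec(n = 10000)
  perf <- closed_form_performance(spec)
  cohort <- simulate_cohort(spec, seed = 7)
  dec <- ifelse(cohort$score <= 7, "impaired", "intact")
  cm <- confusion_from_predictions(dec, cohort$status, positive = "impaired")
  m <- metrics_from_confusion(cm)
  n_imp <- sum(cohort$status == "impaired")
  n_int <- nrow(cohort) - n_imp
  se <- function(p, n) sqrt(p * (1 - p) / n)
  expect_lt(abs(m[["sensitivity"]] - perf$metrics[["sensitivity"]]),
            3 * se(perf$metrics[["sensitivity"]], n_imp))
  expect_lt(abs(m[["specificity"]] - perf$metrics[["specificity"]]),
            3 * se(perf$metrics[["specificity"]], n_int))
  expect_lt(abs(m[["accuracy"]] - perf$metrics[["accuracy"]]),
            3 * se(perf$metrics[["accuracy"]], nrow(cohort)))
  auc_emp <- roc_auc(roc_curve(cohort$score, cohort$status))
  auc_se <- sqrt(hanley_mcneil_variance(perf$auc, n_imp, n_int))
  expect_lt(abs(auc_emp - perf$auc), 3 * auc_se)
})

test_that("cohort CSV round-trips", {
  cohort <- simulate_cohort(cohort_spec(n = 25), seed = 9)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(cohort, tmp)
  back <- read_cohort_csv(tmp)
  expect_equal(as.data.frame(cohort), as.data.frame(back))
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_cohort_csv(bad), "missing column")
})

test_that("spec validation rejects impairment that improves performance", {
  expect_error(cohort_spec(p_incorrect = matrix(
    c(0.5, 0.5, 0.5, 0.1, 0.5, 0.5), nrow = 2, byrow = TRUE,
    dimnames = list(c("intact", "impaired"),
                    c("cube", "infinity", "clock")))),
    "improve")
  expect_error(cohort_spec(prevalence = 1.2), "probabilities")
})
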