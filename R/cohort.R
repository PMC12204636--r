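#' Specification of a simulated screening cohort
#'
#' Describes the generative model of a patient cohort with the structure the
#' screening validation assumes: cognitive status drawn Bernoulli(prevalence),
#' per-task drawing failures conditionally independent given status (with
#' impaired patients failing at least as often), totals scored under the
#' 2/1/5 rubric, and demographic covariates drawn from categorical/normal
#' marginals. Defaults reproduce the published cohort's structure: 17/46
#' impairment prevalence; age 49.1 (SD 15.0) years; 52% female; 78%/17%/4%
#' secondary/postsecondary/less-than-secondary education; 63% employed;
#' ethnicity 67% Caucasian, 13% Indigenous, 9% Indian, 7% Filipino, 2%
#' African, 2% European; 76% examined with ACE-3. Covariates are null by
#' default — they do not influence scores — so regression specificity is
#' testable; score effects can be injected via `covariate_effects`.
#'
#' The default per-task incorrect-rates (intact 0.10/0.15/0.10, impaired
#' 0.55/0.50/0.65 for cube/infinity/clock) place the all-correct probability
#' near 0.69 for intact and 0.08 for impaired patients, matching the
#' screening operating point the validation framework is exercised at.
#'
#' @param n Number of patients.
#' @param prevalence Probability of impairment (default 17/46).
#' @param p_incorrect 2 x 3 numeric matrix of per-task incorrect
#'   probabilities, rows `intact` and `impaired`, columns `cube`, `infinity`,
#'   `clock`. Impaired rates must be >= intact rates task-wise.
#' @param age_mean,age_sd Age model (years), shared across statuses by
#'   default.
#' @param p_female Probability of sex `"female"`.
#' @param p_education,p_ethnicity Named category probabilities (sum to 1).
#' @param p_employed Probability of employment status `"employed"`.
#' @param p_ace3 Probability the reference exam is `"ACE-3"` (vs `"MoCA"`).
#' @param covariate_effects Optional named numeric vector of additive score
#'   effects for injected-signal simulations, e.g.
#'   `c(age = -0.05, "age:status" = -0.02)`; see [simulate_cohort()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 46L,
                        prevalence = 17 / 46,
                        p_incorrect = default_p_incorrect(),
                        age_mean = 49.1, age_sd = 15.0,
                        p_female = 24 / 46,
                        p_education = c(secondary = 36, postsecondary = 8,
                                        less_than_secondary = 2) / 46,
                        p_ethnicity = c(Caucasian = 31, Indigenous = 6,
                                        Indian = 4, Filipino = 3,
                                        African = 1, European = 1) / 46,
                        p_employed = 29 / 46,
                        p_ace3 = 35 / 46,
                        covariate_effects = NULL) {
  p_incorrect <- as.matrix(p_incorrect)
  if (!all(rownames(p_incorrect) == c("intact", "impaired")) ||
      !all(colnames(p_incorrect) == c("cube", "infinity", "clock"))) {
    stop("p_incorrect must have rows intact, impaired and columns ",
         "cube, infinity, clock", call. = FALSE)
  }
  probs <- c(prevalence, p_incorrect, p_female, p_education, p_ethnicity,
             p_employed, p_ace3)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(p_incorrect["impaired", ] < p_incorrect["intact", ])) {
    stop("impairment must not improve performance: need ",
         "p_incorrect[impaired, ] >= p_incorrect[intact, ] per task",
         call. = FALSE)
  }
  if (abs(sum(p_education) - 1) > 1e-9 || abs(sum(p_ethnicity) - 1) > 1e-9) {
    stop("category probabilities must sum to 1", call. = FALSE)
  }
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  structure(list(n = as.integer(n), prevalence = prevalence,
                 p_incorrect = p_incorrect,
                 age_mean = age_mean, age_sd = age_sd,
                 p_female = p_female, p_education = p_education,
                 p_ethnicity = p_ethnicity, p_employed = p_employed,
                 p_ace3 = p_ace3, covariate_effects = covariate_effects),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_p_incorrect <- function() {
  matrix(c(0.10, 0.15, 0.10,
           0.55, 0.50, 0.65),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("intact", "impaired"),
                         c("cube", "infinity", "clock")))
}

#' Simulate a patient cohort
#'
#' Draws a cohort under a [cohort_spec()]: status, per-task correctness,
#' battery totals under the rubric, and covariates. When
#' `spec$covariate_effects` is set, the named effects are added to the score
#' as-is and the total becomes continuous (`status` refers to the impaired
#' indicator; `"a:b"` names an interaction; `sex` counts female as 1,
#' `employment` employed as 1) — a deliberately simple device for
#' regression power studies, where an exactly known additive effect matters
#' more than rubric-integer totals.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @param rubric A [task_rubric()].
#' @return A data.frame of class `patient_cohort`: columns `id`, `status`,
#'   `cube`, `infinity`, `clock` (logical correctness), `score`, `age`,
#'   `sex`, `education`, `employment`, `ethnicity`, `exam`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = NULL,
                            rubric = task_rubric()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n
  impaired <- stats::runif(n) < spec$prevalence
  status <- ifelse(impaired, "impaired", "intact")
  correct <- sapply(c("cube", "infinity", "clock"), function(task) {
    p_inc <- spec$p_incorrect[ifelse(impaired, "impaired", "intact"), task]
    stats::runif(n) >= p_inc
  })
  if (n == 1L) correct <- matrix(correct, nrow = 1,
                                 dimnames = list(NULL, c("cube", "infinity",
                                                         "clock")))
  score <- vapply(seq_len(n), function(i) {
    score_battery(c(cube = correct[i, "cube"],
                    infinity = correct[i, "infinity"],
                    clock = correct[i, "clock"]), rubric)
  }, integer(1))
  cat_draw <- function(p) names(p)[1L + findInterval(stats::runif(n),
                                                     cumsum(p))]
  cohort <- data.frame(
    id = seq_len(n),
    status = status,
    cube = correct[, "cube"],
    infinity = correct[, "infinity"],
    clock = correct[, "clock"],
    score = score,
    age = round(stats::rnorm(n, spec$age_mean, spec$age_sd), 1),
    sex = ifelse(stats::runif(n) < spec$p_female, "female", "male"),
    education = cat_draw(spec$p_education),
    employment = ifelse(stats::runif(n) < spec$p_employed,
                        "employed", "unemployed"),
    ethnicity = cat_draw(spec$p_ethnicity),
    exam = ifelse(stats::runif(n) < spec$p_ace3, "ACE-3", "MoCA"),
    stringsAsFactors = FALSE
  )
  if (!is.null(spec$covariate_effects)) {
    num <- function(v) switch(v,
      status = as.numeric(impaired),
      age = cohort$age,
      sex = as.numeric(cohort$sex == "female"),
      employment = as.numeric(cohort$employment == "employed"),
      exam = as.numeric(cohort$exam == "ACE-3"),
      stop("unsupported effect variable '", v, "'", call. = FALSE))
    shift <- numeric(n)
    for (term in names(spec$covariate_effects)) {
      vars <- strsplit(term, ":", fixed = TRUE)[[1]]
      x <- Reduce(`*`, lapply(vars, num))
      shift <- shift + spec$covariate_effects[[term]] * x
    }
    cohort$score <- cohort$score + shift
  }
  class(cohort) <- c("patient_cohort", "data.frame")
  cohort
}

#' Exact screening performance by enumeration
#'
#' Computes the expected screening metrics of a cohort model without any
#' simulation: the 8 per-task correctness patterns are enumerated for each
#' status (pattern probabilities multiply across tasks by conditional
#' independence), scored under the rubric, and the decision rule applied.
#' The AUC is the exact concordance `P(S_impaired < S_intact) + P(tie)/2`
#' of the two score distributions (low score ranks as positive). Serves as
#' the analytic oracle that Monte-Carlo cohorts must converge to.
#'
#' @param spec A [cohort_spec()] (only `prevalence` and `p_incorrect` are
#'   used).
#' @param policy A [screen_policy()].
#' @param rubric A [task_rubric()].
#' @return A list of class `closed_form_performance`: `metrics` (a
#'   [metrics_from_confusion()] vector), `auc`, `confusion` (probability
#'   form), and the per-status score distributions `score_pmf` (matrix,
#'   columns `intact`/`impaired`, rows scores `0..max_total`).
#' @export
closed_form_performance <- function(spec = cohort_spec(),
                                    policy = screen_policy(),
                                    rubric = task_rubric()) {
  stopifnot(inherits(spec, "cohort_spec"))
  tasks <- c("cube", "infinity", "clock")
  pats <- as.matrix(expand.grid(cube = c(FALSE, TRUE),
                                infinity = c(FALSE, TRUE),
                                clock = c(FALSE, TRUE)))
  scores <- apply(pats, 1L, function(p) sum(rubric$points[tasks][p]))
  mt <- rubric$max_total
  pmf <- matrix(0, nrow = mt + 1L, ncol = 2,
                dimnames = list(0:mt, c("intact", "impaired")))
  for (st in colnames(pmf)) {
    p_inc <- spec$p_incorrect[st, tasks]
    pr <- apply(pats, 1L, function(p) {
      prod(ifelse(p, 1 - p_inc, p_inc))
    })
    for (i in seq_along(scores)) {
      pmf[scores[i] + 1L, st] <- pmf[scores[i] + 1L, st] + pr[i]
    }
  }
  pos_given <- function(st) {      # P(screen positive | status)
    s <- 0:mt
    keep <- if (policy$rule == "le") s <= policy$threshold
            else s < policy$threshold
    sum(pmf[keep, st])
  }
  prev <- spec$prevalence
  sens <- pos_given("impaired")
  spc <- 1 - pos_given("intact")
  cm <- binary_confusion(tp = prev * sens,
                         fp = (1 - prev) * (1 - spc),
                         fn = prev * (1 - sens),
                         tn = (1 - prev) * spc,
                         type = "probability")
  # exact Mann-Whitney concordance of the two score distributions
  p_imp <- pmf[, "impaired"]; p_int <- pmf[, "intact"]
  conc <- 0
  for (a in 0:mt) {
    for (b in 0:mt) {
      w <- if (a < b) 1 else if (a == b) 0.5 else 0
      conc <- conc + w * p_imp[a + 1L] * p_int[b + 1L]
    }
  }
  structure(list(metrics = metrics_from_confusion(cm), auc = unname(conc),
                 confusion = cm, score_pmf = pmf,
                 policy = policy),
            class = "closed_form_performance")
}

#' @export
print.closed_form_performance <- function(x, ...) {
  cat("<closed_form_performance>\n")
  print(round(unclass(x$metrics), 4))
  cat(sprintf("AUC = %.4f\n", x$auc))
  invisible(x)
}

#' Write or read a cohort as CSV
#'
#' @param cohort A `patient_cohort` data.frame.
#' @param path CSV file path.
#' @return `write_cohort_csv()` returns `path` invisibly; `read_cohort_csv()`
#'   a `patient_cohort`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "status", "cube", "infinity", "clock", "score")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("cohort file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (task in c("cube", "infinity", "clock")) {
    cohort[[task]] <- as.logical(cohort[[task]])
  }
  class(cohort) <- c("patient_cohort", "data.frame")
  cohort
}
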