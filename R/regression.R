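#' Ordinary least squares of covariates on the battery score
#'
#' Fits `score ~ age + ethnicity + sex + education + employment + exam +
#' status` by OLS, the all-covariates model used to ask which patient
#' factors (if any) influence the battery score beyond cognitive status.
#' Categorical covariates enter as reference-level indicators with the most
#' frequent level as the reference; age is not centered. No multiplicity
#' adjustment is applied across terms.
#'
#' @param cohort A `patient_cohort` data.frame (see [simulate_cohort()]).
#' @param covariates Predictors to include (default: all six demographic
#'   covariates plus cognitive status).
#' @return An object of class `roca_regression`: a coefficient table
#'   `terms` (`term`, `estimate`, `std_error`, `p_value`), `n`, `r_squared`,
#'   `sigma2`, a `degenerate` flag (constant response), and the underlying
#'   `lm` fit.
#' @export
fit_all_covariates <- function(cohort,
                               covariates = c("age", "ethnicity", "sex",
                                              "education", "employment",
                                              "exam", "status")) {
  fit_score_regression(cohort, covariates, interactions = NULL)
}

#' Interaction of one covariate with cognitive status
#'
#' Regresses the score on one covariate, cognitive status, and their
#' interaction — the per-covariate model asking whether a patient factor
#' compounds the effect of impaired cognition. Run once per covariate.
#'
#' @param cohort A `patient_cohort` data.frame.
#' @param covariate Name of the covariate to cross with status.
#' @return An object of class `roca_regression` (see
#'   [fit_all_covariates()]); the interaction rows are the terms containing
#'   `:`.
#' @export
fit_interaction <- function(cohort, covariate) {
  stopifnot(length(covariate) == 1L)
  fit_score_regression(cohort, c(covariate, "status"),
                       interactions = paste0(covariate, ":status"))
}

fit_score_regression <- function(cohort, covariates, interactions) {
  stopifnot(is.data.frame(cohort), "score" %in% names(cohort))
  miss <- setdiff(covariates, names(cohort))
  if (length(miss)) {
    stop("cohort lacks covariate(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dat <- cohort[, c("score", covariates), drop = FALSE]
  for (v in covariates) {
    if (is.character(dat[[v]]) || is.factor(dat[[v]]) ||
        is.logical(dat[[v]])) {
      x <- as.character(dat[[v]])
      if (length(unique(x)) < 2L) {
        stop("covariate '", v, "' has a single level", call. = FALSE)
      }
      ref <- names(sort(table(x), decreasing = TRUE))[1]
      dat[[v]] <- stats::relevel(factor(x), ref = ref)
    } else if (length(unique(dat[[v]])) < 2L) {
      stop("covariate '", v, "' has a single value", call. = FALSE)
    }
  }
  rhs <- paste(c(covariates, interactions), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("score ~", rhs)), data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("design is rank deficient; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  degenerate <- stats::var(dat$score) == 0
  sm <- summary(fit)
  tab <- stats::coef(sm)
  terms <- data.frame(term = rownames(tab),
                      estimate = tab[, "Estimate"],
                      std_error = tab[, "Std. Error"],
                      p_value = tab[, "Pr(>|t|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  if (degenerate) {             # constant response: slopes exactly 0, no fit
    terms$estimate[terms$term != "(Intercept)"] <- 0
    terms$p_value <- NA_real_
  }
  structure(list(terms = terms, n = nrow(dat),
                 r_squared = if (degenerate) NA_real_ else sm$r.squared,
                 sigma2 = sm$sigma^2, degenerate = degenerate, fit = fit),
            class = "roca_regression")
}

#' @export
print.roca_regression <- function(x, ...) {
  cat(sprintf("<roca_regression> n=%d R^2=%s%s\n", x$n,
              if (is.na(x$r_squared)) "NA" else sprintf("%.3f", x$r_squared),
              if (x$degenerate) " (degenerate: constant score)" else ""))
  print(transform(x$terms, estimate = round(estimate, 4),
                  std_error = round(std_error, 4),
                  p_value = signif(p_value, 3)), row.names = FALSE)
  invisible(x)
}
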