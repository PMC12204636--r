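#' Binary confusion matrix
#'
#' Holds TP/FP/FN/TN either as counts (a cohort cross-tabulation) or as cell
#' probabilities (a chance model), with "positive" meaning screen-positive /
#' impaired throughout.
#'
#' @param tp,fp,fn,tn Non-negative cell values.
#' @param type `"count"` or `"probability"`; guessed from the total when
#'   omitted. Probability cells must sum to 1 (tolerance 1e-9).
#' @return An object of class `binary_confusion`.
#' @export
binary_confusion <- function(tp, fp, fn, tn, type = NULL) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(cells) || any(cells < 0)) {
    stop("confusion cells must be non-negative", call. = FALSE)
  }
  total <- sum(cells)
  if (is.null(type)) {
    type <- if (abs(total - 1) < 1e-9) "probability" else "count"
  }
  type <- match.arg(type, c("count", "probability"))
  if (type == "probability" && abs(total - 1) > 1e-9) {
    stop("probability confusion cells must sum to 1", call. = FALSE)
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 total = total, type = type),
            class = "binary_confusion")
}

#' @export
print.binary_confusion <- function(x, ...) {
  cat(sprintf("<binary_confusion (%s)> TP=%g FP=%g FN=%g TN=%g\n",
              x$type, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Cross-tabulate predicted against true binary labels
#'
#' @param predicted,truth Equal-length vectors of labels; entries equal to
#'   `positive` count as positive, everything else as negative.
#' @param positive The positive-class label (default `"positive"`).
#' @return A [binary_confusion()] of counts.
#' @export
confusion_from_predictions <- function(predicted, truth,
                                       positive = "positive") {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have the same length", call. = FALSE)
  }
  pp <- as.character(predicted) == positive
  tt <- as.character(truth) == positive
  binary_confusion(tp = sum(pp & tt), fp = sum(pp & !tt),
                   fn = sum(!pp & tt), tn = sum(!pp & !tt), type = "count")
}

#' Screening metrics from a confusion matrix
#'
#' Computes accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, PPV `TP/(TP+FP)` and NPV `TN/(TN+FN)`. A zero denominator
#' yields `NA` for that metric (flagged in the `undefined` attribute), never
#' an error, so sweeps over extreme thresholds always complete.
#'
#' @param cm A [binary_confusion()] (counts or probabilities).
#' @return A named numeric vector of class `screening_metrics`.
#' @examples
#' m <- metrics_from_confusion(binary_confusion(16, 10, 1, 19))
#' round(m[["sensitivity"]], 2)  # 0.94
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "binary_confusion"))
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  m <- c(accuracy    = safe_div(cm$tp + cm$tn, cm$total),
         sensitivity = safe_div(cm$tp, cm$tp + cm$fn),
         specificity = safe_div(cm$tn, cm$tn + cm$fp),
         ppv         = safe_div(cm$tp, cm$tp + cm$fp),
         npv         = safe_div(cm$tn, cm$tn + cm$fn))
  structure(m, undefined = names(m)[is.na(m)],
            class = c("screening_metrics", "numeric"))
}

#' @export
print.screening_metrics <- function(x, ...) {
  cat("<screening_metrics>\n")
  print(round(unclass(x), 4), ...)
  if (length(attr(x, "undefined"))) {
    cat("undefined (zero denominator):",
        paste(attr(x, "undefined"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Random-classifier chance model
#'
#' The chance-level baseline for a classifier that predicts independently of
#' its input: the joint cell probability of (predicted class i, true class j)
#' is the selection probability `q[i]` times the class prior `p[j]`. With
#' uniform `q` over two classes, chance accuracy and sensitivity are both
#' 50% regardless of the prior, and chance NPV equals the negative-class
#' prior — e.g. 29/46 (63%) under a 17-impaired / 29-intact cohort.
#'
#' @param q Selection probabilities over predicted classes (sums to 1).
#'   Default: uniform over `c(positive, negative)`.
#' @param p Class priors over true classes, same length and order as `q`
#'   (sums to 1).
#' @return An object of class `chance_model`.
#' @seealso [chance_confusion()]
#' @export
chance_model <- function(q = c(positive = 0.5, negative = 0.5), p) {
  q <- as.numeric(q) / 1; p <- as.numeric(p) / 1
  if (length(q) != length(p)) {
    stop("q and p must have the same number of classes", call. = FALSE)
  }
  if (length(q) < 2L) stop("need at least two classes", call. = FALSE)
  if (any(q < 0) || any(p < 0) ||
      abs(sum(q) - 1) > 1e-9 || abs(sum(p) - 1) > 1e-9) {
    stop("q and p must each be non-negative and sum to 1", call. = FALSE)
  }
  structure(list(q = q, p = p), class = "chance_model")
}

#' Expected confusion matrix and metrics of a random classifier
#'
#' Builds the probability matrix `cell[i, j] = q[i] * p[j]`. For the binary
#' case (class order: positive, negative) the result carries a
#' [binary_confusion()] in probability form plus its [metrics_from_confusion()]
#' metrics; for K > 2 classes it carries the K x K matrix and the expected
#' multiclass accuracy `sum(q * p)`.
#'
#' @param model A [chance_model()].
#' @return A list of class `chance_confusion` with elements `cells`,
#'   `accuracy`, and (binary case) `confusion` and `metrics`.
#' @export
chance_confusion <- function(model) {
  stopifnot(inherits(model, "chance_model"))
  cells <- outer(model$q, model$p)
  acc <- sum(model$q * model$p)
  out <- list(cells = cells, accuracy = acc)
  if (length(model$q) == 2L) {
    cm <- binary_confusion(tp = cells[1, 1], fp = cells[1, 2],
                           fn = cells[2, 1], tn = cells[2, 2],
                           type = "probability")
    out$confusion <- cm
    out$metrics <- metrics_from_confusion(cm)
  }
  structure(out, class = "chance_confusion")
}

#' ROC curve for a low-score-is-positive screening score
#'
#' Sweeps every achievable threshold `t` of the rule "screen positive iff
#' score <= t" (orientation `"low"`; `"high"` flips the rule to `>=`). The
#' curve has one point per distinct score plus a strictest sentinel at which
#' nobody screens positive, ordered from strictest to loosest, and its AUC is
#' the trapezoidal area over (FPR, sensitivity) — identical to the
#' Mann-Whitney concordance probability with ties counted 1/2.
#'
#' @param scores Numeric scores, one per subject.
#' @param truth True labels; entries equal to `positive` are the positive
#'   (impaired) class. Both classes must be present.
#' @param positive Positive-class label (default `"impaired"`).
#' @param orientation `"low"` (low score indicates the positive class,
#'   default) or `"high"`.
#' @return A data.frame of class `roc_curve` with columns `threshold`,
#'   `sensitivity`, `specificity`, `fpr`, `youden_j`, and attribute `auc`.
#' @export
roc_curve <- function(scores, truth, positive = "impaired",
                      orientation = c("low", "high")) {
  orientation <- match.arg(orientation)
  if (length(scores) != length(truth)) {
    stop("scores and truth must have the same length", call. = FALSE)
  }
  pos <- as.character(truth) == positive
  if (!any(pos) || all(pos)) {
    stop("need at least one positive and one negative subject", call. = FALSE)
  }
  s <- if (orientation == "low") as.numeric(scores) else -as.numeric(scores)
  uniq <- sort(unique(s))
  thr <- c(-Inf, uniq)  # -Inf sentinel: nobody screens positive
  sens <- vapply(thr, function(t) mean(s[pos] <= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(s[!pos] <= t), numeric(1))
  shown <- if (orientation == "low") thr else -thr
  out <- data.frame(threshold = shown, sensitivity = sens,
                    specificity = 1 - fpr, fpr = fpr,
                    youden_j = sens - fpr)
  attr(out, "auc") <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  attr(out, "orientation") <- orientation
  attr(out, "positive") <- positive
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' Area under a ROC curve
#'
#' @param roc A [roc_curve()].
#' @return The trapezoidal AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  attr(roc, "auc")
}

#' Youden-index optimal threshold
#'
#' Returns the threshold maximizing `J = sensitivity + specificity - 1`,
#' breaking ties toward the strictest threshold (the one screening the
#' fewest subjects positive).
#'
#' @param roc A [roc_curve()].
#' @return A list with `threshold` and `j`.
#' @export
youden_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  j <- roc$youden_j
  best <- which(j >= max(j) - 1e-12)[1]  # rows are ordered strictest first
  list(threshold = roc$threshold[best], j = j[best])
}

#' Percentile bootstrap of a statistic
#'
#' Resamples the records with replacement (same n), evaluates the statistic
#' on each resample, and reads the confidence limits from the percentile
#' quantiles. Resamples on which the statistic is undefined (`NA` or an
#' error, e.g. a single-class resample) are redrawn; the count of redraws is
#' reported. Deterministic for a given `seed`.
#'
#' @param data A vector or data.frame of records; data.frames are resampled
#'   by row (the patient is the resampling unit for diagnostic statistics).
#' @param statistic Function mapping a resample of `data` to a scalar.
#' @param n_boot Number of bootstrap resamples (1000 for drawing-level, or
#'   10000 for diagnostic-level inference).
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @param level Confidence level (default 0.95).
#' @return An object of class `bootstrap_result`: `estimate` (statistic on
#'   the original sample), `boot_mean`, `ci_low`, `ci_high`, `level`,
#'   `n_boot`, `seed`, `n_redrawn`, and the resampled `values`.
#' @export
bootstrap_statistic <- function(data, statistic, n_boot = 1000L,
                                seed = NULL, level = 0.95) {
  n <- NROW(data)
  if (n < 2L) stop("need at least 2 records to bootstrap", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  take <- function(idx) if (is.data.frame(data)) data[idx, , drop = FALSE]
                        else data[idx]
  est <- statistic(data)
  values <- numeric(n_boot)
  n_redrawn <- 0L
  max_attempts <- 100L * n_boot
  attempts <- 0L
  b <- 1L
  while (b <= n_boot) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("statistic undefined on too many resamples", call. = FALSE)
    }
    v <- tryCatch(statistic(take(sample.int(n, n, replace = TRUE))),
                  error = function(e) NA_real_)
    if (is.na(v)) { n_redrawn <- n_redrawn + 1L; next }
    values[b] <- v
    b <- b + 1L
  }
  alpha <- 1 - level
  ci <- stats::quantile(values, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  structure(list(estimate = est, boot_mean = mean(values),
                 ci_low = ci[1], ci_high = ci[2], level = level,
                 n_boot = n_boot, seed = seed, n_redrawn = n_redrawn,
                 values = values),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> estimate=%.4f %g%% CI [%.4f, %.4f] (n_boot=%d%s)\n",
              x$estimate, 100 * x$level, x$ci_low, x$ci_high, x$n_boot,
              if (x$n_redrawn > 0) sprintf(", %d redrawn", x$n_redrawn) else ""))
  invisible(x)
}

#' Bootstrap p-value against a chance-level baseline
#'
#' Bootstraps the statistic and counts how often it falls at or below the
#' chance value: `p = #(boot <= chance) / n_boot`. A zero count is reported
#' with the resolution floor `1/n_boot` (the p-value is then best stated as
#' `< 1/n_boot`).
#'
#' @inheritParams bootstrap_statistic
#' @param chance_value The chance-level value of the statistic (e.g. 0.5 for
#'   an AUC).
#' @return A list of class `chance_p`: `p`, `count`, `n_boot`, `p_floor`,
#'   `below_floor`, `label`, and the underlying `bootstrap` result.
#' @export
p_vs_chance <- function(data, statistic, chance_value, n_boot = 1000L,
                        seed = NULL) {
  boot <- bootstrap_statistic(data, statistic, n_boot = n_boot, seed = seed)
  count <- sum(boot$values <= chance_value)
  p <- count / n_boot
  structure(list(p = p, count = count, n_boot = n_boot,
                 p_floor = 1 / n_boot, below_floor = count == 0L,
                 label = if (count == 0L) sprintf("< %g", 1 / n_boot)
                         else format(p),
                 chance_value = chance_value, bootstrap = boot),
            class = "chance_p")
}

#' @export
print.chance_p <- function(x, ...) {
  cat(sprintf("<chance_p> p %s vs chance %g (count %d / %d)\n",
              if (x$below_floor) x$label else sprintf("= %s", x$label),
              x$chance_value, x$count, x$n_boot))
  invisible(x)
}

# Vectorized screening metrics over all thresholds 0..max_total for one
# (sub)sample, from per-score cumulative counts. Rows: metrics; cols: t.
sweep_metric_matrix <- function(score, impaired, max_total) {
  k <- max_total + 1L
  cimp <- cumsum(tabulate(score[impaired] + 1L, nbins = k))
  cint <- cumsum(tabulate(score[!impaired] + 1L, nbins = k))
  nimp <- sum(impaired); nint <- sum(!impaired)
  tp <- cimp; fp <- cint; fn <- nimp - cimp; tn <- nint - cint
  div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  rbind(accuracy    = (tp + tn) / (nimp + nint),
        sensitivity = div(tp, tp + fn),
        specificity = div(tn, tn + fp),
        ppv         = div(tp, tp + fp),
        npv         = div(tn, tn + fn))
}

#' Screening metrics with bootstrap confidence bands at every threshold
#'
#' For every threshold `t` in `0..max_total` of the rule "positive iff score
#' <= t", computes the five screening metrics on the cohort and their
#' percentile-bootstrap confidence intervals (resampling patients with
#' replacement; each resample is evaluated at all thresholds). Identifies the
#' screening-optimal threshold: the one maximizing sensitivity and NPV
#' jointly (largest sensitivity + NPV, metrics undefined at a threshold drop
#' it from the ranking; ties go to the strictest threshold).
#'
#' @param cohort Data.frame with columns `score` (integer totals) and
#'   `status` (`"impaired"` / `"intact"`); both statuses must be present.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @param level Confidence level.
#' @param rubric A [task_rubric()] (defines `max_total`).
#' @return A data.frame of class `threshold_sweep` with columns `threshold`,
#'   `metric`, `estimate`, `ci_low`, `ci_high`; the optimum is in attribute
#'   `best` (list with `threshold`, `sensitivity`, `npv`).
#' @export
threshold_sweep <- function(cohort, n_boot = 1000L, seed = NULL,
                            level = 0.95, rubric = task_rubric()) {
  stopifnot(is.data.frame(cohort), all(c("score", "status") %in% names(cohort)))
  impaired <- cohort$status == "impaired"
  if (!any(impaired) || all(impaired)) {
    stop("cohort must contain both impaired and intact patients",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  mt <- rubric$max_total
  score <- as.integer(cohort$score)
  point <- sweep_metric_matrix(score, impaired, mt)
  n <- length(score)
  boots <- array(NA_real_, dim = c(nrow(point), mt + 1L, n_boot))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boots[, , b] <- sweep_metric_matrix(score[idx], impaired[idx], mt)
  }
  alpha <- 1 - level
  qs <- apply(boots, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) c(NA_real_, NA_real_)
    else stats::quantile(v, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  })
  metrics <- rownames(point)
  out <- data.frame(
    threshold = rep(0:mt, each = length(metrics)),
    metric = rep(metrics, times = mt + 1L),
    estimate = as.vector(point),
    ci_low = as.vector(qs[1, , ]),
    ci_high = as.vector(qs[2, , ])
  )
  joint <- point["sensitivity", ] + point["npv", ]
  best_t <- if (all(is.na(joint))) NA_integer_
            else (which(joint >= max(joint, na.rm = TRUE) - 1e-12)[1] - 1L)
  attr(out, "best") <- list(threshold = best_t,
                            sensitivity = unname(point["sensitivity",
                                                       best_t + 1L]),
                            npv = unname(point["npv", best_t + 1L]))
  attr(out, "level") <- level
  attr(out, "n_boot") <- n_boot
  class(out) <- c("threshold_sweep", "data.frame")
  out
}

#' Hanley-McNeil AUC variance components
#'
#' `Q1 = A / (2 - A)`, `Q2 = 2 A^2 / (1 + A)`, and the AUC variance
#' `V = [A(1-A) + (n1-1)(Q1 - A^2) + (n2-1)(Q2 - A^2)] / (n1 n2)` for `n1`
#' positive and `n2` negative cases.
#'
#' @param auc The ROC area `A`.
#' @param n1,n2 Positive- and negative-group sizes.
#' @return `hanley_mcneil_variance()` returns the variance; `hanley_mcneil_q()`
#'   the list `(q1, q2)`.
#' @export
hanley_mcneil_variance <- function(auc, n1, n2) {
  q <- hanley_mcneil_q(auc)
  (auc * (1 - auc) + (n1 - 1) * (q$q1 - auc^2) +
     (n2 - 1) * (q$q2 - auc^2)) / (n1 * n2)
}

#' @rdname hanley_mcneil_variance
#' @export
hanley_mcneil_q <- function(auc) {
  list(q1 = auc / (2 - auc), q2 = 2 * auc^2 / (1 + auc))
}

#' Sample size per group for detecting an AUC above chance
#'
#' Finds the smallest equal group size `n` at which a z-test of the null
#' `AUC = 0.5` against the alternative `AUC = A` attains the requested power:
#' the smallest `n` with
#' `A - 0.5 >= z_alpha * sqrt(V(0.5, n, n)) + z_power * sqrt(V(A, n, n))`,
#' using the Hanley-McNeil variance under both hypotheses. Alpha is one-sided
#' by default; sidedness, alpha and power are exposed because published
#' sample-size statements frequently omit them.
#'
#' @param auc Target AUC `A`, strictly between 0.5 and 1.
#' @param alpha Significance level (default 0.05).
#' @param power Required power (default 0.8).
#' @param sided 1 (default) or 2.
#' @return A list of class `hanley_mcneil` exposing `n_per_group`, `q1`,
#'   `q2`, `var_alt`, `var_null`, `z_alpha`, `z_power` and the inputs.
#' @export
hanley_mcneil_n <- function(auc, alpha = 0.05, power = 0.8, sided = 1) {
  if (!is.finite(auc) || auc <= 0.5 || auc >= 1) {
    stop("auc must lie strictly between 0.5 and 1", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must lie in (0, 1)", call. = FALSE)
  }
  sided <- match.arg(as.character(sided), c("1", "2"))
  z_alpha <- stats::qnorm(1 - alpha / as.numeric(sided))
  z_power <- stats::qnorm(power)
  delta <- auc - 0.5
  ok <- function(n) {
    delta >= z_alpha * sqrt(hanley_mcneil_variance(0.5, n, n)) +
      z_power * sqrt(hanley_mcneil_variance(auc, n, n))
  }
  hi <- 2L
  while (!ok(hi)) {
    hi <- hi * 2L
    if (hi > 1e8) stop("required sample size exceeds 1e8", call. = FALSE)
  }
  lo <- max(2L, hi %/% 2L)
  while (lo < hi) {            # first n in (lo, hi] satisfying ok()
    mid <- (lo + hi) %/% 2L
    if (ok(mid)) hi <- mid else lo <- mid + 1L
  }
  n <- hi
  q <- hanley_mcneil_q(auc)
  structure(list(n_per_group = n, auc = auc, alpha = alpha, power = power,
                 sided = as.integer(as.numeric(sided)),
                 q1 = q$q1, q2 = q$q2,
                 var_alt = hanley_mcneil_variance(auc, n, n),
                 var_null = hanley_mcneil_variance(0.5, n, n),
                 z_alpha = z_alpha, z_power = z_power),
            class = "hanley_mcneil")
}

#' @export
print.hanley_mcneil <- function(x, ...) {
  cat(sprintf("<hanley_mcneil> AUC=%.2f alpha=%.3f (%d-sided) power=%.2f -> n=%d per group\n",
              x$auc, x$alpha, x$sided, x$power, x$n_per_group))
  invisible(x)
}
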