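#' The battery point rubric
#'
#' The three-task drawing battery awards full points or zero per task: a
#' correct cube copy is worth 2 points, correct overlapping infinities 1
#' point, and a correct clock 5 points, for a maximum total of 8. There is no
#' partial credit.
#'
#' @param cube,infinity,clock Points awarded for a correct drawing of each
#'   task; all must be positive.
#' @return An object of class `task_rubric` with fields `points` (named
#'   vector) and `max_total`.
#' @examples
#' r <- task_rubric()
#' r$max_total  # 8
#' @export
task_rubric <- function(cube = 2L, infinity = 1L, clock = 5L) {
  pts <- c(cube = as.integer(cube), infinity = as.integer(infinity),
           clock = as.integer(clock))
  if (any(pts <= 0L)) stop("all task points must be positive", call. = FALSE)
  structure(list(points = pts, max_total = sum(pts)), class = "task_rubric")
}

#' Threshold-based screening decision rule
#'
#' A screening policy converts a battery total into a screen decision:
#' a patient screens positive (possibly impaired) when their score falls at
#' or below the threshold. The default threshold of 7 out of 8 means only a
#' perfect battery screens negative — the highly sensitive cut a screening
#' (rule-out) examination wants. The strict variant (`rule = "lt"`, positive
#' iff score < t) is selectable.
#'
#' @param threshold Score threshold `t`, in `0..max_total`.
#' @param rule `"le"` (positive iff score <= t, default) or `"lt"`.
#' @param rubric The [task_rubric()] defining the score range.
#' @return An object of class `screen_policy`.
#' @export
screen_policy <- function(threshold = 7L, rule = c("le", "lt"),
                          rubric = task_rubric()) {
  rule <- match.arg(rule)
  threshold <- as.integer(threshold)
  if (threshold < 0L || threshold > rubric$max_total) {
    stop("threshold must be in 0..", rubric$max_total, call. = FALSE)
  }
  structure(list(threshold = threshold, rule = rule), class = "screen_policy")
}

#' Score a completed battery
#'
#' @param correct Named logical vector with entries `cube`, `infinity`,
#'   `clock`: whether each drawing was judged correct.
#' @param rubric A [task_rubric()].
#' @return Integer total score in `0..max_total`.
#' @examples
#' score_battery(c(cube = TRUE, infinity = FALSE, clock = TRUE))  # 7
#' @export
score_battery <- function(correct, rubric = task_rubric()) {
  tasks <- names(rubric$points)
  if (!all(tasks %in% names(correct))) {
    missing <- setdiff(tasks, names(correct))
    stop("missing task(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  correct <- correct[tasks]
  if (anyNA(correct) || !is.logical(correct)) {
    stop("per-task correctness must be TRUE/FALSE for every task",
         call. = FALSE)
  }
  as.integer(sum(rubric$points[correct]))
}

#' Apply a screening policy to a battery total
#'
#' @param score Integer total in `0..max_total`.
#' @param policy A [screen_policy()].
#' @param rubric A [task_rubric()].
#' @return `"positive"` (screens impaired) or `"negative"` (screens intact),
#'   with the decision rule attached as attribute `rule`.
#' @export
screen_decision <- function(score, policy = screen_policy(),
                            rubric = task_rubric()) {
  if (length(score) != 1L || is.na(score) ||
      score < 0 || score > rubric$max_total || score != round(score)) {
    stop("score must be a single integer in 0..", rubric$max_total,
         call. = FALSE)
  }
  positive <- if (policy$rule == "le") score <= policy$threshold
              else score < policy$threshold
  structure(if (positive) "positive" else "negative",
            rule = sprintf("positive iff score %s %d",
                           if (policy$rule == "le") "<=" else "<",
                           policy$threshold))
}

#' All achievable battery totals
#'
#' Enumerates the 8 correct/incorrect patterns and returns the sorted set of
#' achievable totals. Under the default 2/1/5 rubric this is
#' `{0, 1, 2, 3, 5, 6, 7, 8}` — a total of 4 is unreachable.
#'
#' @param rubric A [task_rubric()].
#' @return Sorted integer vector of achievable totals.
#' @export
score_support <- function(rubric = task_rubric()) {
  pats <- expand.grid(cube = c(FALSE, TRUE), infinity = c(FALSE, TRUE),
                      clock = c(FALSE, TRUE))
  totals <- apply(pats, 1L, function(p) {
    score_battery(c(cube = p[["cube"]], infinity = p[["infinity"]],
                    clock = p[["clock"]]), rubric)
  })
  sort(unique(as.integer(totals)))
}
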