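#' Read a synthetic dataset written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.csv` and stroke-JSON files.
#' @return A list of class `synth_dataset` (distortion specs are not
#'   round-tripped; labels carry `task`, `correct`, `seed`).
#' @export
read_dataset <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) {
    stop("no manifest.csv in '", dir, "'", call. = FALSE)
  }
  man <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(man)), function(i) {
    list(drawing = read_drawing(file.path(dir, man$file[i])),
         label = list(task = man$task[i], correct = as.logical(man$correct[i]),
                      distortion = NULL, seed = man$seed[i]))
  })
  structure(out, class = "synth_dataset")
}

#' End-to-end pipeline configuration
#'
#' A single reproducible description of the full experiment: synthesize
#' labeled drawings, train the classifier, simulate a patient cohort, score
#' each simulated patient's battery through the classifier, and run the
#' screening evaluation. A master `seed` is mandatory; all stage seeds are
#' derived from it deterministically, so rerunning the same config
#' reproduces the report. Round-trips through a JSON file via
#' [write_run_config()] / [read_run_config()].
#'
#' @param seed Master integer seed (required).
#' @param n_per_cell Training drawings per task x correctness cell.
#' @param correct_fraction Fraction of correct drawings per task.
#' @param epochs,batch_size,learning_rate,validation_fraction Training
#'   hyperparameters (see [train_spec()]).
#' @param input_size Network input raster side.
#' @param cohort_n Simulated cohort size.
#' @param prevalence Impairment prevalence of the simulated cohort.
#' @param threshold Screening threshold (see [screen_policy()]).
#' @param n_boot Bootstrap resamples for the evaluation stage.
#' @param level Confidence level.
#' @param holdout_per_cell Drawings per cell in the held-out classifier
#'   evaluation set.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed, n_per_cell = 200L, correct_fraction = 0.5,
                       epochs = 15L, batch_size = 16L, learning_rate = 5e-3,
                       validation_fraction = 0.2, input_size = 96L,
                       cohort_n = 46L, prevalence = 17 / 46,
                       threshold = 7L, n_boot = 1000L, level = 0.95,
                       holdout_per_cell = 25L) {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(
        as.integer(seed)))) {
    stop("run_config requires an explicit integer seed", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_per_cell = as.integer(n_per_cell),
                 correct_fraction = correct_fraction,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 validation_fraction = validation_fraction,
                 input_size = as.integer(input_size),
                 cohort_n = as.integer(cohort_n), prevalence = prevalence,
                 threshold = as.integer(threshold),
                 n_boot = as.integer(n_boot), level = level,
                 holdout_per_cell = as.integer(holdout_per_cell)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::fromJSON(path)
  if (is.null(vals$seed)) {
    stop("config file lacks the mandatory seed", call. = FALSE)
  }
  do.call(run_config, vals)
}

# deterministic stage seeds derived from the master seed
stage_seeds <- function(seed) {
  offs <- c(synth = 101L, net = 211L, train = 307L, holdout = 401L,
            cohort = 503L, drawings = 601L, eval = 701L)
  as.list((as.integer(seed) * 97L + offs) %% 2147483629L + 1L)
}

# classify one generated battery per patient: returns the classifier-derived
# score per cohort row
score_cohort_drawings <- function(model, cohort, seed,
                                  rubric = task_rubric()) {
  set.seed(seed)
  base <- sample.int(2147480000L, nrow(cohort) * 3L)
  tasks <- c("cube", "infinity", "clock")
  scores <- integer(nrow(cohort))
  k <- 0L
  for (i in seq_len(nrow(cohort))) {
    pred <- logical(3)
    names(pred) <- tasks
    for (task in tasks) {
      k <- k + 1L
      want <- isTRUE(cohort[[task]][i])
      for (attempt in 0:49) {
        s <- (base[k] + 7919L * attempt) %% 2147483629L + 1L
        set.seed(s)
        dist <- if (want) sample_correct_distortion()
                else sample_incorrect_distortion(task)
        d <- generate_drawing(task, dist, seed = s + 1L)
        if (drawing_is_correct(d) == want) break
      }
      pred[task] <- classify(model, d)$condensed == "correct"
    }
    scores[i] <- score_battery(pred, rubric)
  }
  scores
}

#' Run the full screening experiment
#'
#' Executes synth, training, classifier evaluation on a held-out synthetic
#' set, cohort simulation, per-patient battery scoring through the
#' classifier, and the screening evaluation (ROC/AUC point and bootstrap,
#' Youden threshold, chance baselines, p-value vs chance, threshold sweep,
#' all-covariates regression). Any stage failure aborts with the stage name
#' and cause. Rerunning the same config reproduces the report except for
#' its timestamp.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, the report, the cohort CSV
#'   and the model checkpoint are written there along with a manifest of
#'   seeds and versions.
#' @return A list of class `pipeline_report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- stage_seeds(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  train_set <- stage("synth", generate_labeled_dataset(
    config$n_per_cell, config$correct_fraction, seed = seeds$synth))
  model <- stage("train", {
    net <- build_sketchnet(net_config(input_size = config$input_size,
                                      seed = seeds$net))
    train_sketchnet(net, train_set,
                    train_spec(epochs = config$epochs,
                               batch_size = config$batch_size,
                               learning_rate = config$learning_rate,
                               validation_fraction =
                                 config$validation_fraction,
                               seed = seeds$train))
  })
  holdout <- stage("holdout", generate_labeled_dataset(
    config$holdout_per_cell, config$correct_fraction, seed = seeds$holdout))
  drawing_eval <- stage("classifier-evaluation",
                        evaluate_classifier(model, holdout))
  cohort <- stage("cohort", simulate_cohort(
    cohort_spec(n = config$cohort_n, prevalence = config$prevalence),
    seed = seeds$cohort))
  roca_score <- stage("battery-scoring",
                      score_cohort_drawings(model, cohort, seeds$drawings))
  cohort$roca_score <- roca_score
  evaluation <- stage("evaluation", {
    eval_cohort <- data.frame(score = roca_score, status = cohort$status)
    roc <- roc_curve(eval_cohort$score, eval_cohort$status)
    boot_auc <- bootstrap_statistic(
      eval_cohort, function(d) roc_auc(roc_curve(d$score, d$status)),
      n_boot = config$n_boot, seed = seeds$eval, level = config$level)
    p_auc <- mean(boot_auc$values <= 0.5)
    prev <- mean(eval_cohort$status == "impaired")
    chance <- chance_confusion(chance_model(p = c(prev, 1 - prev)))
    sweep <- threshold_sweep(eval_cohort, n_boot = config$n_boot,
                             seed = seeds$eval, level = config$level)
    reg_cohort <- cohort
    reg_cohort$score <- roca_score
    # small cohorts can sample a covariate at a single level; drop those
    covs <- c("age", "ethnicity", "sex", "education", "employment",
              "exam", "status")
    covs <- covs[vapply(covs, function(v)
      length(unique(reg_cohort[[v]])) >= 2L, logical(1))]
    list(roc = as.data.frame(roc), auc_point = roc_auc(roc),
         auc_boot_mean = boot_auc$boot_mean,
         auc_ci = c(boot_auc$ci_low, boot_auc$ci_high),
         p_auc_vs_chance = if (p_auc == 0) paste0("< ", 1 / config$n_boot)
                           else p_auc,
         youden = youden_threshold(roc),
         chance_metrics = unclass(chance$metrics),
         sweep = as.data.frame(sweep),
         sweep_best = attr(sweep, "best"),
         regression = fit_all_covariates(reg_cohort, covariates = covs)$terms)
  })
  report <- structure(list(
    config = unclass(config),
    seeds = seeds,
    versions = list(package = as.character(utils::packageVersion("roca")),
                    r = as.character(getRversion())),
    training_report = model$report,
    drawing_evaluation = list(
      per_task = lapply(drawing_eval$per_task, function(t) {
        list(confusion = unclass(t$confusion)[c("tp", "fp", "fn", "tn")],
             metrics = unclass(t$metrics))
      }),
      overall_accuracy = drawing_eval$overall$metrics[["accuracy"]]),
    cohort = as.data.frame(cohort),
    evaluation = evaluation,
    timestamp = format(Sys.time(), tz = "UTC")
  ), class = "pipeline_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    save_sketchnet(model, file.path(out_dir, "model.rds"))
    write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
    writeLines(jsonlite::toJSON(report[setdiff(names(report), "cohort")],
                                auto_unbox = TRUE, digits = NA,
                                dataframe = "rows", force = TRUE),
               file.path(out_dir, "report.json"))
    writeLines(jsonlite::toJSON(list(seeds = seeds,
                                     versions = report$versions,
                                     timestamp = report$timestamp),
                                auto_unbox = TRUE),
               file.path(out_dir, "manifest.json"))
  }
  report
}

# ---- command-line interface ------------------------------------------------

parse_cli_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      stop("unexpected argument '", a, "'", call. = FALSE)
    }
    key <- gsub("-", "_", substring(a, 3L))
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1L
    } else {
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  flags
}

cli_num <- function(flags, key, default = NULL) {
  if (is.null(flags[[key]])) {
    if (is.null(default)) stop("missing required flag --",
                               gsub("_", "-", key), call. = FALSE)
    return(default)
  }
  as.numeric(flags[[key]])
}

cli_chr <- function(flags, key, default = NULL) {
  if (is.null(flags[[key]])) {
    if (is.null(default)) stop("missing required flag --",
                               gsub("_", "-", key), call. = FALSE)
    return(default)
  }
  as.character(flags[[key]])
}

cli_emit <- function(x, out = NULL) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", force = TRUE)
  if (is.null(out)) cat(json, "\n", sep = "") else writeLines(json, out)
}

#' Command-line entry point
#'
#' Dispatches the `roca` subcommands (`synth`, `train`, `classify`, `score`,
#' `simulate-cohort`, `evaluate`, `sweep`, `samplesize`, `regress`, `run`)
#' over the package's functions; results go to files or stdout as JSON/CSV,
#' diagnostics to stderr. The installed script `inst/cli/roca` forwards
#' `commandArgs()` here.
#'
#' @param args Character vector of command-line arguments (subcommand
#'   first).
#' @return Integer exit status (0 on success), invisibly.
#' @export
roca_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) {
      stop("usage: roca <synth|train|classify|score|simulate-cohort|",
           "evaluate|sweep|samplesize|regress|run> [--flags]",
           call. = FALSE)
    }
    cmd <- args[1]
    flags <- parse_cli_flags(args[-1])
    switch(cmd,
      synth = {
        ds <- generate_labeled_dataset(
          n_per_cell = cli_num(flags, "n_per_cell"),
          correct_fraction = cli_num(flags, "correct_fraction", 0.5),
          seed = cli_num(flags, "seed"))
        write_dataset(ds, cli_chr(flags, "out"))
        message("wrote ", length(ds), " drawings to ", cli_chr(flags, "out"))
      },
      train = {
        ds <- read_dataset(cli_chr(flags, "data"))
        model <- build_sketchnet(net_config(seed = cli_num(flags, "seed")))
        model <- train_sketchnet(model, ds, train_spec(
          epochs = cli_num(flags, "epochs", 15),
          seed = cli_num(flags, "seed")))
        save_sketchnet(model, cli_chr(flags, "out"))
        message("final validation accuracy: ",
                round(utils::tail(model$report$val_acc, 1), 3))
      },
      classify = {
        model <- load_sketchnet(cli_chr(flags, "model"))
        res <- classify(model, read_drawing(cli_chr(flags, "in")))
        cli_emit(unclass(res), flags$out)
      },
      score = {
        model <- load_sketchnet(cli_chr(flags, "model"))
        paths <- strsplit(cli_chr(flags, "drawings"), ",")[[1]]
        rubric <- task_rubric()
        correct <- logical(0)
        for (p in paths) {
          d <- read_drawing(p)
          correct[d$task] <- classify(model, d)$condensed == "correct"
        }
        total <- score_battery(correct, rubric)
        policy <- screen_policy(cli_num(flags, "threshold", 7))
        dec <- screen_decision(total, policy, rubric)
        cli_emit(list(per_task_correct = as.list(correct),
                      per_task_points = as.list(
                        rubric$points[names(correct)] * correct),
                      total = total, decision = as.character(dec),
                      policy = attr(dec, "rule")), flags$out)
      },
      `simulate-cohort` = {
        spec <- cohort_spec(n = cli_num(flags, "n", 46),
                            prevalence = cli_num(flags, "prevalence",
                                                 17 / 46))
        cohort <- simulate_cohort(spec, seed = cli_num(flags, "seed"))
        write_cohort_csv(cohort, cli_chr(flags, "out"))
        message("wrote cohort of ", nrow(cohort), " patients")
      },
      evaluate = {
        cohort <- read_cohort_csv(cli_chr(flags, "cohort"))
        seed <- cli_num(flags, "seed")
        n_boot <- cli_num(flags, "n_boot", 1000)
        policy <- screen_policy(cli_num(flags, "threshold", 7))
        dec <- ifelse(
          vapply(cohort$score, function(s)
            as.character(screen_decision(s, policy)), character(1)) ==
            "positive", "impaired", "intact")
        cm <- confusion_from_predictions(dec, cohort$status,
                                         positive = "impaired")
        roc <- roc_curve(cohort$score, cohort$status)
        boot <- bootstrap_statistic(
          cohort, function(d) roc_auc(roc_curve(d$score, d$status)),
          n_boot = n_boot, seed = seed)
        prev <- mean(cohort$status == "impaired")
        chance <- chance_confusion(chance_model(p = c(prev, 1 - prev)))
        cli_emit(list(
          confusion = unclass(cm)[c("tp", "fp", "fn", "tn")],
          metrics = as.list(unclass(metrics_from_confusion(cm))),
          auc_point = roc_auc(roc), auc_boot_mean = boot$boot_mean,
          auc_ci = c(boot$ci_low, boot$ci_high),
          p_auc_vs_chance = mean(boot$values <= 0.5),
          youden = youden_threshold(roc),
          chance_metrics = as.list(unclass(chance$metrics)),
          n_boot = n_boot, seed = seed), flags$out)
      },
      sweep = {
        cohort <- read_cohort_csv(cli_chr(flags, "cohort"))
        sw <- threshold_sweep(cohort, n_boot = cli_num(flags, "n_boot", 1000),
                              seed = cli_num(flags, "seed"))
        cli_emit(list(sweep = as.data.frame(sw),
                      best = attr(sw, "best")), flags$out)
      },
      samplesize = {
        res <- hanley_mcneil_n(auc = cli_num(flags, "auc"),
                               alpha = cli_num(flags, "alpha", 0.05),
                               power = cli_num(flags, "power", 0.8),
                               sided = cli_num(flags, "sided", 1))
        cli_emit(unclass(res), flags$out)
      },
      regress = {
        cohort <- read_cohort_csv(cli_chr(flags, "cohort"))
        mode <- cli_chr(flags, "mode", "all")
        fit <- if (mode == "all") fit_all_covariates(cohort)
               else fit_interaction(cohort, cli_chr(flags, "covariate"))
        cli_emit(list(terms = fit$terms, n = fit$n,
                      r_squared = fit$r_squared), flags$out)
      },
      run = {
        config <- read_run_config(cli_chr(flags, "config"))
        run_pipeline(config, out_dir = cli_chr(flags, "out"))
        message("pipeline complete; report in ", cli_chr(flags, "out"))
      },
      stop("unknown subcommand '", cmd, "'", call. = FALSE)
    )
    0L
  }, error = function(e) {
    message("roca: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
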