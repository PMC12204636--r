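#' Default class inventory of the sketch classifier
#'
#' The classifier is inherently multiclass: one class per task x correctness
#' cell, condensed to correct/incorrect per task after prediction.
#'
#' @param tasks Tasks to cross with `{correct, incorrect}`.
#' @return Character vector like `"cube_correct"`, `"cube_incorrect"`, ...
#' @export
sketch_classes <- function(tasks = drawing_tasks()) {
  as.vector(t(outer(tasks, c("correct", "incorrect"), paste, sep = "_")))
}

#' Condense multiclass predictions to correct/incorrect
#'
#' Total deterministic mapping: class names ending in `"_correct"` condense
#' to `"correct"`, everything else to `"incorrect"`.
#'
#' @param class_name Character vector of class names.
#' @return Character vector of `"correct"` / `"incorrect"`.
#' @export
condense_class <- function(class_name) {
  ifelse(endsWith(as.character(class_name), "_correct"),
         "correct", "incorrect")
}

#' Architecture of the sketch classifier
#'
#' A compact fire-module convolutional network: a strided stem convolution,
#' a stack of fire modules (1x1 squeeze convolution feeding parallel 1x1 and
#' 3x3 expand convolutions concatenated along channels) with 2x2 max-pool
#' downsampling after selected modules, a 1x1 convolution to one channel per
#' class, global average pooling and softmax. The default — 3 fire modules
#' on 96x96 input — is a reduced stack sized for desktop-CPU training;
#' larger stacks are expressible through the same configuration.
#'
#' @param input_size Side of the square input raster (px).
#' @param class_names Ordered class inventory (default [sketch_classes()]).
#' @param stem_channels Channels of the stem convolution.
#' @param fire_specs List of `c(squeeze, expand1, expand3)` triples; each
#'   must satisfy `squeeze < expand1 + expand3`.
#' @param pool_after Indices of fire modules followed by 2x2 max pooling
#'   (the stem is always followed by one pooling stage).
#' @param seed Seed for parameter initialization.
#' @return An object of class `net_config`.
#' @export
net_config <- function(input_size = 96L,
                       class_names = sketch_classes(),
                       stem_channels = 8L,
                       fire_specs = list(c(4L, 8L, 8L), c(8L, 16L, 16L),
                                         c(8L, 16L, 16L)),
                       pool_after = c(1L, 2L),
                       seed = 42L) {
  class_names <- as.character(class_names)
  if (length(class_names) < 2L || anyDuplicated(class_names)) {
    stop("class_names must be at least two unique names", call. = FALSE)
  }
  if (length(fire_specs) < 1L) {
    stop("need at least one fire module", call. = FALSE)
  }
  for (fs in fire_specs) {
    if (length(fs) != 3L || any(fs < 1L)) {
      stop("each fire spec is c(squeeze, expand1, expand3), all >= 1",
           call. = FALSE)
    }
    if (fs[1] >= fs[2] + fs[3]) {
      stop("fire module invariant violated: squeeze channels (", fs[1],
           ") must be < expand channels (", fs[2], " + ", fs[3], ")",
           call. = FALSE)
    }
  }
  if (any(pool_after < 1L) || any(pool_after > length(fire_specs))) {
    stop("pool_after must index into fire_specs", call. = FALSE)
  }
  structure(list(input_size = as.integer(input_size),
                 class_names = class_names,
                 stem_channels = as.integer(stem_channels),
                 fire_specs = lapply(fire_specs, as.integer),
                 pool_after = as.integer(pool_after),
                 seed = as.integer(seed)),
            class = "net_config")
}

#' Build an untrained sketch classifier
#'
#' Instantiates the network described by a [net_config()] with seeded
#' He-normal initialization; two builds from the same config (same seed)
#' have identical initial parameters.
#'
#' @param config A [net_config()].
#' @return An object of class `sketchnet` (untrained).
#' @export
build_sketchnet <- function(config = net_config()) {
  stopifnot(inherits(config, "net_config"))
  set.seed(config$seed)
  size <- config$input_size
  layers <- list()
  stem_geom <- make_conv_geom(size, size, 1L, 3L, 2L, 1L)
  layers[[1]] <- new_conv_layer(stem_geom, config$stem_channels, relu = TRUE)
  size <- stem_geom$Hout
  layers[[2]] <- new_pool_layer(size, size)
  size <- size %/% 2L
  C <- config$stem_channels
  for (i in seq_along(config$fire_specs)) {
    fs <- config$fire_specs[[i]]
    layers[[length(layers) + 1L]] <-
      new_fire_layer(size, size, C, fs[1], fs[2], fs[3])
    C <- fs[2] + fs[3]
    if (i %in% config$pool_after) {
      layers[[length(layers) + 1L]] <- new_pool_layer(size, size)
      size <- size %/% 2L
    }
  }
  head_geom <- make_conv_geom(size, size, C, 1L, 1L, 0L)
  layers[[length(layers) + 1L]] <-
    new_conv_layer(head_geom, length(config$class_names), relu = FALSE)
  structure(list(config = config, layers = layers, trained = FALSE,
                 report = NULL, format_version = 1L),
            class = "sketchnet")
}

#' @export
print.sketchnet <- function(x, ...) {
  np <- 0
  count <- function(cl) length(cl$W) + length(cl$b)
  for (l in x$layers) {
    np <- np + switch(l$type, conv = count(l),
                      fire = count(l$squeeze) + count(l$e1) + count(l$e3), 0)
  }
  cat(sprintf("<sketchnet> %d classes, %d fire modules, %s, %d parameters\n",
              length(x$config$class_names), length(x$config$fire_specs),
              if (x$trained) "trained" else "untrained", np))
  invisible(x)
}

#' Training hyperparameters
#'
#' @param epochs Training epochs (>= 1).
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam learning rate.
#' @param validation_fraction Fraction of the data held out for per-epoch
#'   validation accuracy, strictly in (0, 1).
#' @param seed Seed for the split, shuffling and any augmentation.
#' @param pretrained_source Optional path to a saved [sketchnet] checkpoint
#'   whose weights initialize training (a transfer-learning hook; the
#'   default is training from scratch, which requires no external weights).
#' @return An object of class `train_spec`.
#' @export
train_spec <- function(epochs = 15L, batch_size = 16L, learning_rate = 5e-3,
                       validation_fraction = 0.2, seed = 7L,
                       pretrained_source = NULL) {
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop("validation_fraction must lie strictly between 0 and 1",
         call. = FALSE)
  }
  if (batch_size < 1L || learning_rate <= 0) {
    stop("batch_size must be >= 1 and learning_rate > 0", call. = FALSE)
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed),
                 pretrained_source = pretrained_source),
            class = "train_spec")
}

#' Rasterize and preprocess a labeled dataset for the classifier
#'
#' @param dataset A [generate_labeled_dataset()] result, or any list of
#'   elements with `drawing` and `label` fields.
#' @param spec A [preprocess_spec()]; its `out_size` must match the network
#'   input size used later.
#' @return A list with `x` (array `out_size x out_size x 1 x N`) and `y`
#'   (character class names `task_correct` / `task_incorrect`).
#' @export
prepare_classifier_data <- function(dataset, spec = preprocess_spec()) {
  n <- length(dataset)
  x <- array(0, dim = c(spec$out_size, spec$out_size, 1L, n))
  y <- character(n)
  for (i in seq_len(n)) {
    item <- dataset[[i]]
    r <- preprocess(rasterize(item$drawing, spec), spec)
    x[, , 1L, i] <- r$pixels
    y[i] <- paste0(item$label$task, "_",
                   if (item$label$correct) "correct" else "incorrect")
  }
  list(x = x, y = y)
}

#' Train the sketch classifier
#'
#' Minimizes softmax cross-entropy by seeded mini-batch Adam. The data are
#' split stratified-by-class into training and validation parts; the report
#' records per-epoch training loss and training/validation accuracy.
#' Identical seed, spec and data give identical reports — the
#' implementation is plain single-threaded R with no nondeterministic
#' kernels, which the report flags as `deterministic = TRUE`.
#'
#' @param model An untrained (or previously trained) [build_sketchnet()]
#'   model.
#' @param data A list with `x` (input array `S x S x 1 x N`, `S` the config
#'   input size) and `y` (class labels), as from
#'   [prepare_classifier_data()]; or a `synth_dataset`, which is prepared
#'   automatically at the model's input size.
#' @param spec A [train_spec()].
#' @return The trained `sketchnet`; `$report` holds the training report
#'   (data.frame `epoch`, `train_loss`, `train_acc`, `val_acc`, plus
#'   attributes `deterministic` and `n_train`/`n_val`).
#' @export
train_sketchnet <- function(model, data, spec = train_spec()) {
  stopifnot(inherits(model, "sketchnet"), inherits(spec, "train_spec"))
  if (inherits(data, "synth_dataset")) {
    data <- prepare_classifier_data(
      data, preprocess_spec(out_size = model$config$input_size))
  }
  x <- data$x; y <- as.character(data$y)
  classes <- model$config$class_names
  if (!all(y %in% classes)) {
    stop("labels outside the configured classes: ",
         paste(setdiff(unique(y), classes), collapse = ", "), call. = FALSE)
  }
  if (dim(x)[1] != model$config$input_size ||
      dim(x)[2] != model$config$input_size) {
    stop("input size ", dim(x)[1], "x", dim(x)[2], " does not match the ",
         "configured ", model$config$input_size, call. = FALSE)
  }
  if (!is.null(spec$pretrained_source)) {
    pre <- load_sketchnet(spec$pretrained_source)
    model$layers <- pre$layers
  }
  set.seed(spec$seed)
  n <- length(y)
  # stratified split; every class must appear in the training part
  val_idx <- unlist(lapply(split(seq_len(n), y), function(ix) {
    nv <- floor(spec$validation_fraction * length(ix))
    if (nv >= 1L) sample(ix, nv) else integer(0)
  }), use.names = FALSE)
  train_idx <- setdiff(seq_len(n), val_idx)
  missing_cls <- setdiff(classes, unique(y[train_idx]))
  if (length(missing_cls)) {
    stop("class(es) absent from the training split: ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  y_num <- match(y, classes)
  K <- length(classes)
  states <- lapply(model$layers, adam_init_like)
  t_adam <- 0L
  report <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       train_acc = numeric(0), val_acc = numeric(0))
  for (epoch in seq_len(spec$epochs)) {
    order_idx <- sample(train_idx)
    losses <- numeric(0); correct <- 0L
    for (start in seq(1L, length(order_idx), by = spec$batch_size)) {
      batch <- order_idx[start:min(start + spec$batch_size - 1L,
                                   length(order_idx))]
      xb <- x[, , , batch, drop = FALSE]
      yb <- y_num[batch]
      fwd <- net_forward(model, xb, keep_caches = TRUE)
      P <- softmax_cols(fwd$logits)
      nb <- length(batch)
      picked <- P[cbind(yb, seq_len(nb))]
      losses <- c(losses, -mean(log(pmax(picked, 1e-12))))
      correct <- correct + sum(apply(P, 2L, which.max) == yb)
      dZ <- P
      dZ[cbind(yb, seq_len(nb))] <- dZ[cbind(yb, seq_len(nb))] - 1
      dZ <- dZ / nb
      grads <- net_backward(model, fwd, dZ)
      t_adam <- t_adam + 1L
      for (i in seq_along(model$layers)) {
        r <- adam_step_layer(model$layers[[i]], grads[[i]], states[[i]],
                             spec$learning_rate, t_adam)
        model$layers[[i]] <- r$layer
        states[i] <- list(r$state)  # pool layers carry no optimizer state
      }
    }
    val_acc <- if (length(val_idx)) {
      pv <- predict_classes(model, x[, , , val_idx, drop = FALSE])
      mean(pv == y_num[val_idx])
    } else NA_real_
    report <- rbind(report, data.frame(epoch = epoch,
                                       train_loss = mean(losses),
                                       train_acc = correct /
                                         length(train_idx),
                                       val_acc = val_acc))
  }
  attr(report, "deterministic") <- TRUE
  attr(report, "n_train") <- length(train_idx)
  attr(report, "n_val") <- length(val_idx)
  model$trained <- TRUE
  model$report <- report
  model
}

# predicted class indices for an input array, batched to bound memory
predict_classes <- function(model, x, batch_size = 64L) {
  n <- dim(x)[4]
  out <- integer(n)
  for (start in seq(1L, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1L, n)
    Z <- net_forward(model, x[, , , ix, drop = FALSE])$logits
    out[ix] <- apply(Z, 2L, which.max)
  }
  out
}

#' Classify a preprocessed raster
#'
#' @param model A trained [sketchnet].
#' @param image A [raster_image()] of the network's input size (as produced
#'   by [preprocess()]), or a [stroke_drawing()] which is rasterized and
#'   preprocessed automatically.
#' @return A list of class `classifier_output`: `probabilities` (named,
#'   sums to 1), `predicted_class` (argmax), `condensed` (`"correct"` /
#'   `"incorrect"`).
#' @export
classify <- function(model, image) {
  stopifnot(inherits(model, "sketchnet"))
  if (inherits(image, "stroke_drawing")) {
    ps <- preprocess_spec(out_size = model$config$input_size)
    image <- preprocess(rasterize(image, ps), ps)
  }
  stopifnot(inherits(image, "raster_image"))
  S <- model$config$input_size
  if (image$height != S || image$width != S) {
    stop("input raster is ", image$height, "x", image$width,
         " but the network expects ", S, "x", S, call. = FALSE)
  }
  x <- array(image$pixels, dim = c(S, S, 1L, 1L))
  Z <- net_forward(model, x)$logits[, 1]
  p <- as.vector(softmax_cols(matrix(Z, ncol = 1)))
  names(p) <- model$config$class_names
  pred <- names(p)[which.max(p)]
  structure(list(probabilities = p, predicted_class = pred,
                 condensed = condense_class(pred)),
            class = "classifier_output")
}

#' @export
print.classifier_output <- function(x, ...) {
  cat(sprintf("<classifier_output> %s (condensed: %s), p=%.3f\n",
              x$predicted_class, x$condensed,
              max(x$probabilities)))
  invisible(x)
}

#' Per-task confusion matrices and metrics of the classifier
#'
#' Classifies every drawing in a labeled dataset, condenses the multiclass
#' prediction to correct/incorrect, and cross-tabulates it per task against
#' the generator's labels ("correct" is the positive class). Metrics come
#' from [metrics_from_confusion()].
#'
#' @param model A trained [sketchnet].
#' @param dataset A labeled dataset (see [prepare_classifier_data()]).
#' @param spec A [preprocess_spec()] matching the network input size.
#' @return A list of class `classifier_evaluation`: `per_task` (per task:
#'   `confusion`, `metrics`, `n`), `overall` (pooled), `predictions`
#'   (data.frame `task`, `truth`, `predicted_class`, `condensed`).
#' @export
evaluate_classifier <- function(model, dataset,
                                spec = preprocess_spec(
                                  out_size = model$config$input_size)) {
  dat <- prepare_classifier_data(dataset, spec)
  pred_idx <- predict_classes(model, dat$x)
  pred_class <- model$config$class_names[pred_idx]
  task <- vapply(dataset, function(it) it$label$task, character(1))
  truth <- ifelse(vapply(dataset, function(it) it$label$correct, logical(1)),
                  "correct", "incorrect")
  condensed <- condense_class(pred_class)
  per_task <- lapply(split(seq_along(task), task), function(ix) {
    cm <- confusion_from_predictions(condensed[ix], truth[ix],
                                     positive = "correct")
    list(confusion = cm, metrics = metrics_from_confusion(cm),
         n = length(ix))
  })
  overall_cm <- confusion_from_predictions(condensed, truth,
                                           positive = "correct")
  structure(list(per_task = per_task,
                 overall = list(confusion = overall_cm,
                                metrics = metrics_from_confusion(overall_cm),
                                n = length(task)),
                 predictions = data.frame(task = task, truth = truth,
                                          predicted_class = pred_class,
                                          condensed = condensed,
                                          stringsAsFactors = FALSE)),
            class = "classifier_evaluation")
}

#' @export
print.classifier_evaluation <- function(x, ...) {
  cat("<classifier_evaluation>\n")
  for (task in names(x$per_task)) {
    cat(sprintf("  %-9s accuracy %.3f (n=%d)\n", task,
                x$per_task[[task]]$metrics[["accuracy"]],
                x$per_task[[task]]$n))
  }
  cat(sprintf("  overall   accuracy %.3f (n=%d)\n",
              x$overall$metrics[["accuracy"]], x$overall$n))
  invisible(x)
}

#' Save or load a sketch classifier checkpoint
#'
#' Single-file checkpoint holding the configuration, class names and all
#' weights; the format version is embedded and checked on load.
#'
#' @param model A [sketchnet].
#' @param path Checkpoint file path.
#' @return `save_sketchnet()` returns `path` invisibly; `load_sketchnet()`
#'   the restored model.
#' @export
save_sketchnet <- function(model, path) {
  stopifnot(inherits(model, "sketchnet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_sketchnet
#' @export
load_sketchnet <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "sketchnet") ||
      !identical(model$format_version, 1L)) {
    stop("'", path, "' is not a version-1 sketchnet checkpoint",
         call. = FALSE)
  }
  model
}
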