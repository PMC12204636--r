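test_that("configuration invariants are enforced", {
  expect_error(net_config(fire_specs = list(c(16, 8, 4))),
               "squeeze channels")
  expect_error(net_config(fire_specs = list()), "at least one fire")
  expect_error(net_config(class_names = c("a", "a")), "unique")
  expect_error(train_spec(validation_fraction = 0), "strictly between")
  expect_error(train_spec(validation_fraction = 1), "strictly between")
  expect_error(train_spec(epochs = 0), "epochs")
})

test_that("builds are seed-deterministic and outputs are probabilities", {
  cfg <- tiny_net_config(seed = 77)
  m1 <- build_sketchnet(cfg)
  m2 <- build_sketchnet(cfg)
  expect_identical(m1$layers, m2$layers)
  img <- raster_image(matrix(runif(16 * 16), 16, 16))
  out <- classify(m1, img)
  expect_length(out$probabilities, 6)
  expect_equal(sum(out$probabilities), 1, tolerance = 1e-6)
  expect_identical(out$predicted_class,
                   names(which.max(out$probabilities)))
  expect_identical(classify(m1, img), classify(m1, img))
})

test_that("classification rejects mismatched input sizes", {
  m <- build_sketchnet(tiny_net_config())
  expect_error(classify(m, raster_image(matrix(0.5, 20, 20))), "expects")
})

test_that("condensation is a total mapping from class names", {
  expect_identical(condense_class(c("cube_correct", "clock_incorrect",
                                    "anything_else")),
                   c("correct", "incorrect", "incorrect"))
  out_classes <- sketch_classes()
  expect_setequal(unique(condense_class(out_classes)),
                  c("correct", "incorrect"))
})

test_that("training rejects invalid data and is seed-reproducible", {
  set.seed(5)
  x <- array(runif(16 * 16 * 12), c(16, 16, 1, 12))
  y <- rep(sketch_classes()[1:2], each = 6)
  m <- build_sketchnet(tiny_net_config())
  expect_error(train_sketchnet(m, list(x = x, y = y)), "absent")
  m2 <- build_sketchnet(tiny_net_config(classes = sketch_classes()[1:2]))
  spec <- train_spec(epochs = 2, batch_size = 4, seed = 3)
  r1 <- train_sketchnet(m2, list(x = x, y = y), spec)
  r2 <- train_sketchnet(m2, list(x = x, y = y), spec)
  expect_identical(r1$report, r2$report)
  expect_identical(r1$layers, r2$layers)
  expect_true(attr(r1$report, "deterministic"))
  expect_error(train_sketchnet(m2, list(x = x, y = rep("mystery", 12))),
               "outside the configured classes")
})

test_that("training on a trivially separable set beats multiclass chance", {
  # zero-distortion correct drawings vs heavily stroke-dropped ones
  make <- function(task, correct, seed) {
    dist <- if (correct) distortion_spec()
            else distortion_spec(stroke_drop_prob = 0.7)
    list(drawing = generate_drawing(task, dist, seed = seed),
         label = list(task = task, correct = correct))
  }
  items <- list()
  for (task in drawing_tasks()) {
    for (i in 1:8) {
      items[[length(items) + 1L]] <- make(task, TRUE, 100 + i)
      items[[length(items) + 1L]] <- make(task, FALSE, 200 + i)
    }
  }
  dat <- prepare_classifier_data(items, preprocess_spec(out_size = 16))
  m <- build_sketchnet(tiny_net_config(seed = 15))
  m <- train_sketchnet(m, dat, train_spec(epochs = 12, batch_size = 8,
                                          learning_rate = 8e-3, seed = 16))
  expect_gt(tail(m$report$val_acc, 1), 1 / 6)
})

test_that("classifier evaluation produces per-task confusions that add up", {
  ds <- generate_labeled_dataset(4, 0.5, seed = 55)
  m <- build_sketchnet(net_config(seed = 1))  # untrained is fine here
  ev <- evaluate_classifier(m, ds)
  expect_setequal(names(ev$per_task), drawing_tasks())
  for (task in names(ev$per_task)) {
    expect_equal(ev$per_task[[task]]$confusion$total, 4)
  }
  expect_equal(ev$overall$confusion$total, 12)
  # accuracy is the share of condensed matches, by definition
  agree <- with(ev$predictions, mean(condensed == truth))
  expect_equal(ev$overall$metrics[["accuracy"]], agree)
})

test_that("checkpoints round-trip through disk", {
  m <- build_sketchnet(tiny_net_config(seed = 4))
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_sketchnet(m, tmp)
  back <- load_sketchnet(tmp)
  expect_identical(m$layers, back$layers)
  expect_identical(m$config, back$config)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_sketchnet(bad), "checkpoint")
})
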