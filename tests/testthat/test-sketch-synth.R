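test_that("undistorted cube is exactly the 12 template edges", {
  d <- generate_cube(seed = 123)
  expect_length(d$strokes, 12)
  tpl <- roca:::cube_template()
  ends <- t(vapply(d$strokes, function(s) {
    c(s[1, "x"], s[1, "y"], s[nrow(s), "x"], s[nrow(s), "y"])
  }, numeric(4)))
  want <- t(apply(tpl$edges, 1, function(e) {
    c(tpl$vertices[e[1], ], tpl$vertices[e[2], ])
  }))
  for (k in seq_len(12)) {
    hit <- apply(want, 1, function(w) {
      isTRUE(all.equal(unname(ends[k, ]), unname(w), tolerance = 1e-9)) ||
        isTRUE(all.equal(unname(ends[k, ]), unname(w[c(3, 4, 1, 2)]),
                         tolerance = 1e-9))
    })
    expect_true(any(hit))
    # collinearity: every interior point on the chord
    s <- d$strokes[[k]]
    chord <- c(s[nrow(s), "x"] - s[1, "x"], s[nrow(s), "y"] - s[1, "y"])
    perp <- abs((s[, "x"] - s[1, "x"]) * chord[2] -
                  (s[, "y"] - s[1, "y"]) * chord[1])
    expect_lt(max(perp), 1e-6)
  }
  expect_true(drawing_is_correct(d))
})

test_that("generators honor forced distortions and seed determinism", {
  expect_length(generate_cube(distortion_spec(stroke_drop_prob = 1),
                              seed = 1)$strokes, 0)
  expect_true(isTRUE(all.equal(generate_cube(seed = 7),
                               generate_cube(seed = 7))))
  spec <- distortion_spec(vertex_jitter_sd = 3, wobble_amplitude = 2)
  expect_true(isTRUE(all.equal(generate_infinity(spec, seed = 11),
                               generate_infinity(spec, seed = 11))))
  expect_true(isTRUE(all.equal(generate_clock(spec, seed = 12),
                               generate_clock(spec, seed = 12))))
  expect_false(isTRUE(all.equal(generate_clock(spec, seed = 12),
                                generate_clock(spec, seed = 13))))
})

test_that("undistorted infinities are two closed intersecting lemniscates", {
  d <- generate_infinity(seed = 5)
  expect_length(d$strokes, 2)
  for (s in d$strokes) {
    expect_lt(sqrt(sum((s[1, 1:2] - s[nrow(s), 1:2])^2)), 1e-9)
  }
  P <- d$strokes[[1]][, c("x", "y")]
  Q <- d$strokes[[2]][, c("x", "y")]
  expect_true(roca:::polylines_intersect(P, Q))
  expect_true(roca:::polylines_intersect(P, P, same_curve = TRUE))
  expect_true(drawing_is_correct(d))
})

test_that("large closure gaps open the infinity curves", {
  d <- generate_infinity(distortion_spec(closure_gap = 40), seed = 6)
  for (s in d$strokes) {
    expect_gt(sqrt(sum((s[1, 1:2] - s[nrow(s), 1:2])^2)), 30)
  }
  expect_false(drawing_is_correct(d))
})

test_that("undistorted clock places numerals on the k*30-degree layout", {
  d <- generate_clock(seed = 9)
  expect_length(d$strokes, 15)  # face + 12 numerals + 2 hands
  ctr <- colMeans(d$strokes[[1]][, c("x", "y")])
  ang <- vapply(d$strokes[2:13], function(s) {
    roca:::clock_angle(colMeans(s[, c("x", "y")]), ctr)
  }, numeric(1))
  # every canonical slot k*30 deg occupied exactly once, within 1 degree
  # (glyph centroids sit a fraction of a pixel off their anchor)
  expect_setequal(round(ang / 30) %% 12, 0:11)
  expect_lt(max(roca:::ang_diff(ang, round(ang / 30) * 30)), 1)
  expect_true(drawing_is_correct(d))
})

test_that("clock hand and numeral errors are realized and fail the rubric", {
  miss <- generate_clock(distortion_spec(clock_hand_error = "missing-hand"),
                         seed = 21)
  expect_length(miss$strokes, 14)
  expect_false(drawing_is_correct(miss))

  wrong <- generate_clock(distortion_spec(clock_hand_error = "wrong-time"),
                          seed = 22)
  expect_length(wrong$strokes, 15)
  expect_false(drawing_is_correct(wrong))

  noneright <- generate_clock(distortion_spec(clock_numeral_errors = 12),
                              seed = 23)
  ctr <- colMeans(noneright$strokes[[1]][, c("x", "y")])
  tol <- synth_rubric()$numeral_angle_tol
  sizes <- vapply(noneright$strokes, nrow, integer(1))
  numerals <- noneright$strokes[sizes == 9]   # glyphs are 9-point circles
  for (s in numerals) {
    a <- roca:::clock_angle(colMeans(s[, c("x", "y")]), ctr)
    k <- round(a / 30)
    canonical <- (if (k %% 12 == 0) 12 else k %% 12) * 30
    expect_gt(roca:::ang_diff(a, canonical), 0)  # displaced if present
  }
  expect_false(drawing_is_correct(noneright))
})

test_that("labeled datasets have the requested composition and are sound", {
  ds <- generate_labeled_dataset(10, correct_fraction = 0.5, seed = 31)
  expect_length(ds, 30)
  man <- dataset_manifest(ds)
  expect_equal(sum(man$correct), 15)
  expect_equal(as.vector(table(man$task)), c(10, 10, 10))
  # label soundness: stated label always matches the geometric rubric
  for (item in ds) {
    expect_identical(drawing_is_correct(item$drawing), item$label$correct)
  }
  all1 <- generate_labeled_dataset(4, correct_fraction = 1, seed = 32)
  expect_true(all(dataset_manifest(all1)$correct))
  expect_true(isTRUE(all.equal(
    generate_labeled_dataset(5, 0.4, seed = 33),
    generate_labeled_dataset(5, 0.4, seed = 33), check.attributes = FALSE)))
})

test_that("correctness rate decays monotonically with jitter and drops", {
  pass_rate <- function(spec, n = 60) {
    mean(vapply(seq_len(n), function(i) {
      drawing_is_correct(generate_cube(spec, seed = 1000 + i))
    }, logical(1)))
  }
  jit <- vapply(c(0, 3, 8, 20), function(sd) {
    pass_rate(distortion_spec(vertex_jitter_sd = sd))
  }, numeric(1))
  expect_true(all(diff(jit) <= 0))
  expect_equal(jit[1], 1)
  expect_lt(jit[4], 0.1)
  drp <- vapply(c(0, 0.3, 0.8), function(p) {
    pass_rate(distortion_spec(stroke_drop_prob = p))
  }, numeric(1))
  expect_true(all(diff(drp) <= 0))
})

test_that("datasets round-trip through the on-disk stroke-JSON layout", {
  dir <- withr::local_tempdir()
  ds <- generate_labeled_dataset(3, 0.5, seed = 41)
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_length(back, length(ds))
  for (i in seq_along(ds)) {
    expect_true(isTRUE(all.equal(ds[[i]]$drawing, back[[i]]$drawing)))
    expect_identical(ds[[i]]$label$correct, back[[i]]$label$correct)
  }
})
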