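test_that("stroke JSON serialization round-trips losslessly", {
  tmp <- withr::local_tempfile(fileext = ".json")

  empty <- stroke_drawing("clock")
  write_drawing(empty, tmp)
  expect_true(grepl("\"strokes\":[]", readLines(tmp), fixed = TRUE))
  expect_true(isTRUE(all.equal(empty, read_drawing(tmp))))

  one <- line_drawing()
  write_drawing(one, tmp)
  expect_true(isTRUE(all.equal(one, read_drawing(tmp))))

  full <- generate_clock(distortion_spec(vertex_jitter_sd = 1.5,
                                         wobble_amplitude = 1), seed = 4)
  write_drawing(full, tmp)
  expect_true(isTRUE(all.equal(full, read_drawing(tmp))))
})

test_that("malformed drawing records are rejected with the offending key", {
  tmp <- withr::local_tempfile(fileext = ".json")
  writeLines('{"canvas": {"w": 16, "h": 16}, "strokes": []}', tmp)
  expect_error(read_drawing(tmp), "task")
  writeLines('{"task": "cube", "strokes": []}', tmp)
  expect_error(read_drawing(tmp), "canvas")
})

test_that("drawing invariants are enforced", {
  expect_error(stroke_drawing("cube", list(cbind(x = 20, y = 5, t = 0)),
                              canvas_width = 16, canvas_height = 16),
               "outside the canvas")
  expect_error(stroke_drawing("cube",
                              list(cbind(x = c(1, 2), y = c(1, 2),
                                         t = c(10, 0)))),
               "timestamps")
  expect_error(stroke_drawing("cube", list(matrix(0, 0, 3))), "empty")
})

test_that("rasterization matches a brute-force segment oracle", {
  d <- line_drawing(x0 = 2, x1 = 8, y = 5)
  r <- rasterize(d, preprocess_spec(stroke_thickness = 1))
  got <- which(r$pixels == 1, arr.ind = TRUE)
  # oracle: a thickness-1 horizontal segment marks exactly row y,
  # columns x0..x1 (0-based)
  want <- cbind(row = rep(5 + 1, 7), col = (2:8) + 1)
  expect_equal(got[order(got[, 2]), , drop = FALSE], want,
               ignore_attr = TRUE)
})

test_that("rasterization is deterministic and ink appears iff strokes do", {
  d <- generate_cube(seed = 3)
  expect_identical(rasterize(d)$pixels, rasterize(d)$pixels)
  expect_identical(sum(rasterize(stroke_drawing("cube"))$pixels), 0)
  for (seed in 1:5) {
    di <- generate_infinity(distortion_spec(vertex_jitter_sd = 2),
                            seed = seed)
    expect_gt(sum(rasterize(di)$pixels), 0)
  }
})

test_that("preprocessing centers ink and respects polarity", {
  spec <- preprocess_spec(out_size = 64)
  # ink confined to the top-left quadrant of a 128-canvas
  d <- stroke_drawing("cube",
                      list(cbind(x = c(10, 40), y = c(12, 30), t = c(0, 1))),
                      canvas_width = 128, canvas_height = 128)
  out <- preprocess(rasterize(d, spec), spec)
  hit <- which(out$pixels > 0.5, arr.ind = TRUE)
  ctr <- c(mean(range(hit[, 1])), mean(range(hit[, 2])))
  expect_lt(max(abs(ctr - (1 + 64) / 2)), 1 + 1e-9)

  blank <- raster_image(matrix(0, 32, 32))
  expect_identical(preprocess(blank, spec)$pixels, matrix(0, 64, 64))
  low <- preprocess_spec(out_size = 64, polarity = "ink-low")
  expect_identical(preprocess(blank, low)$pixels, matrix(1, 64, 64))
  inv <- preprocess(rasterize(d, spec), low)
  expect_equal(inv$pixels, 1 - out$pixels, tolerance = 1e-12)
})

test_that("preprocessing is invariant under integer translation of the ink", {
  spec <- preprocess_spec(out_size = 48)
  base <- matrix(0, 100, 100)
  base[30:40, 20:45] <- 1
  base[35, 46:60] <- 1
  shifted <- matrix(0, 100, 100)
  shifted[30:40 + 17, 20:45 + 9] <- 1
  shifted[35 + 17, 46:60 + 9] <- 1
  expect_equal(preprocess(raster_image(base), spec)$pixels,
               preprocess(raster_image(shifted), spec)$pixels,
               tolerance = 1e-12)
})

test_that("preprocessing is numerically stable under reapplication", {
  spec <- preprocess_spec()
  once <- preprocess(rasterize(generate_cube(seed = 8), spec), spec)
  twice <- preprocess(once, spec)
  expect_lt(mean(abs(twice$pixels - once$pixels)), 0.03)
  bb1 <- which(once$pixels > 0.5, arr.ind = TRUE)
  bb2 <- which(twice$pixels > 0.5, arr.ind = TRUE)
  expect_lt(max(abs(apply(bb1, 2, range) - apply(bb2, 2, range))), 3)
})

test_that("rasters round-trip through grayscale PNG", {
  r <- preprocess(rasterize(generate_infinity(seed = 2)))
  tmp <- withr::local_tempfile(fileext = ".png")
  write_raster_png(r, tmp)
  back <- read_raster_png(tmp)
  expect_equal(back$pixels, r$pixels, tolerance = 1 / 254)
})
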