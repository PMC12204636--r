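#' Grayscale raster image
#'
#' A `raster_image` holds a grid of intensities in `[0, 1]`, stored as a
#' numeric matrix with `height` rows and `width` columns; row `r`, column `c`
#' is the pixel at 0-based coordinates `x = c - 1`, `y = r - 1`.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`.
#' @return An object of class `raster_image`.
#' @export
raster_image <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("raster dimensions must be positive", call. = FALSE)
  }
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 1)) {
    stop("raster intensities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(width = ncol(pixels), height = nrow(pixels),
                 pixels = unname(pixels)),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %dx%d ink=%d px\n", x$width, x$height,
              sum(x$pixels > 0)))
  invisible(x)
}

#' Rasterization and preprocessing parameters
#'
#' Controls how stroke drawings become classifier-ready rasters. Defaults:
#' 96x96 output, 2 px stroke thickness, ink-high polarity (ink = 1 on a 0
#' background), 10% margins — small enough for CPU training while keeping
#' strokes visible after downsampling.
#'
#' @param out_size Side of the square preprocessed output, pixels (>= 16).
#' @param stroke_thickness Stroke thickness when rasterizing, pixels (>= 1).
#' @param polarity `"ink-high"` (ink = 1, background 0) or `"ink-low"`.
#' @param margin_fraction Blank margin kept on each side of the centered ink,
#'   as a fraction of `out_size`, in `[0, 0.5)`.
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(out_size = 96L, stroke_thickness = 2L,
                            polarity = c("ink-high", "ink-low"),
                            margin_fraction = 0.1) {
  polarity <- match.arg(polarity)
  out_size <- as.integer(out_size)
  stroke_thickness <- as.integer(stroke_thickness)
  if (out_size < 16L) stop("out_size must be >= 16", call. = FALSE)
  if (stroke_thickness < 1L) stop("stroke_thickness must be >= 1", call. = FALSE)
  if (margin_fraction < 0 || margin_fraction >= 0.5) {
    stop("margin_fraction must be in [0, 0.5)", call. = FALSE)
  }
  structure(list(out_size = out_size, stroke_thickness = stroke_thickness,
                 polarity = polarity, margin_fraction = margin_fraction),
            class = "preprocess_spec")
}

#' Render a stroke drawing onto its canvas
#'
#' Draws every stroke as connected straight segments of the requested
#' thickness, in ink-high form (ink = 1). The output grid has the drawing's
#' canvas dimensions. Rasterization is fully deterministic.
#'
#' @param drawing A valid [stroke_drawing()].
#' @param spec A [preprocess_spec()]; only `stroke_thickness` is used here.
#' @return A [raster_image()] of the canvas.
#' @export
rasterize <- function(drawing, spec = preprocess_spec()) {
  validate_stroke_drawing(drawing)
  stopifnot(inherits(spec, "preprocess_spec"))
  w <- drawing$canvas_width
  h <- drawing$canvas_height
  img <- matrix(0, nrow = h, ncol = w)
  th <- spec$stroke_thickness
  # pixel offsets realizing the thickness as a square pen tip
  off <- seq.int(-((th - 1L) %/% 2L), th %/% 2L)
  for (s in drawing$strokes) {
    for (i in seq_len(max(nrow(s) - 1L, 1L))) {
      p0 <- s[i, 1:2]
      p1 <- s[min(i + 1L, nrow(s)), 1:2]
      len <- sqrt(sum((p1 - p0)^2))
      nstep <- max(2L, ceiling(len / 0.4) + 1L)
      ts <- seq(0, 1, length.out = nstep)
      xs <- round(p0[1] + ts * (p1[1] - p0[1]))
      ys <- round(p0[2] + ts * (p1[2] - p0[2]))
      for (dx in off) {
        for (dy in off) {
          cx <- pmin(pmax(xs + dx, 0), w - 1L)
          cy <- pmin(pmax(ys + dy, 0), h - 1L)
          img[cbind(cy + 1L, cx + 1L)] <- 1
        }
      }
    }
  }
  raster_image(img)
}

# Bounding box (1-based row/col ranges) of pixels above `thr`, or NULL.
ink_bbox <- function(pixels, thr = 0.5) {
  hit <- which(pixels > thr, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(NULL)
  list(r0 = min(hit[, 1]), r1 = max(hit[, 1]),
       c0 = min(hit[, 2]), c1 = max(hit[, 2]))
}

# Bilinear sample of matrix `m` at fractional 1-based coordinates.
bilinear_sample <- function(m, rr, cc) {
  h <- nrow(m); w <- ncol(m)
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  gv <- function(r, c) {
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    out <- numeric(length(r))
    out[ok] <- m[cbind(r[ok], c[ok])]
    out
  }
  gv(r0, c0) * (1 - fr) * (1 - fc) +
    gv(r0 + 1, c0) * fr * (1 - fc) +
    gv(r0, c0 + 1) * (1 - fr) * fc +
    gv(r0 + 1, c0 + 1) * fr * fc
}

#' Center, scale and normalize a raster for classification
#'
#' Finds the ink bounding box (pixels above half intensity), centers it on an
#' `out_size` x `out_size` grid, scales it — aspect ratio preserved, bilinear
#' interpolation — to fit inside the margins, clamps intensities to `[0, 1]`
#' and applies the requested polarity. An all-blank input yields an
#' all-background grid. Output is invariant under integer translation of the
#' input ink (the bounding box moves with it).
#'
#' @param raster A [raster_image()] in ink-high form (as from [rasterize()]).
#' @param spec A [preprocess_spec()].
#' @return A [raster_image()] of side `spec$out_size`.
#' @export
preprocess <- function(raster, spec = preprocess_spec()) {
  stopifnot(inherits(raster, "raster_image"), inherits(spec, "preprocess_spec"))
  S <- spec$out_size
  bb <- ink_bbox(raster$pixels)
  if (is.null(bb)) {
    bg <- if (spec$polarity == "ink-high") 0 else 1
    return(raster_image(matrix(bg, S, S)))
  }
  bw <- bb$c1 - bb$c0 + 1L
  bh <- bb$r1 - bb$r0 + 1L
  target <- S * (1 - 2 * spec$margin_fraction)
  scale <- min(target / bw, target / bh)
  ctr_r <- (bb$r0 + bb$r1) / 2
  ctr_c <- (bb$c0 + bb$c1) / 2
  out_ctr <- (1 + S) / 2
  idx <- seq_len(S)
  src_r <- ctr_r + (idx - out_ctr) / scale
  src_c <- ctr_c + (idx - out_ctr) / scale
  rr <- rep(src_r, times = S)
  cc <- rep(src_c, each = S)
  vals <- bilinear_sample(raster$pixels, rr, cc)
  out <- matrix(pmin(pmax(vals, 0), 1), nrow = S, ncol = S)
  if (spec$polarity == "ink-low") out <- 1 - out
  raster_image(out)
}

#' Read and write rasters as grayscale PNG
#'
#' The interchange format for rasters outside the package is 8-bit grayscale
#' PNG; intensities map linearly to `[0, 1]`.
#'
#' @param raster A [raster_image()].
#' @param path PNG file path.
#' @return `write_raster_png()` returns `path` invisibly; `read_raster_png()`
#'   returns a [raster_image()].
#' @export
write_raster_png <- function(raster, path) {
  stopifnot(inherits(raster, "raster_image"))
  png::writePNG(raster$pixels, target = path)
  invisible(path)
}

#' @rdname write_raster_png
#' @export
read_raster_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]  # collapse grayscale-with-alpha
  raster_image(px)
}
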