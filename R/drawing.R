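#' Stroke-level drawing record
#'
#' A `stroke_drawing` is the raw unit of patient input in the drawing battery:
#' an ordered sequence of pen strokes on a pixel canvas, each stroke an ordered
#' sequence of `(x, y, t)` points with `t` in milliseconds since the start of
#' the drawing. Coordinates use the raster convention: origin at the top-left,
#' `x` rightward, `y` downward, 0-based, so every point must lie within
#' `[0, canvas_width) x [0, canvas_height)`. Timestamps are carried for
#' provenance but ignored by classification (the battery scores static
#' drawings).
#'
#' @param task Which battery item the drawing answers: `"cube"`, `"infinity"`
#'   or `"clock"`.
#' @param strokes List of strokes; each stroke is a numeric matrix (or
#'   data.frame) with columns `x`, `y`, `t`. May be empty (a blank response).
#' @param canvas_width,canvas_height Canvas dimensions in pixels.
#' @return An object of class `stroke_drawing`.
#' @examples
#' d <- stroke_drawing("cube",
#'   list(cbind(x = c(2, 8), y = c(5, 5), t = c(0, 120))),
#'   canvas_width = 16, canvas_height = 16)
#' d
#' @seealso [write_drawing()], [rasterize()]
#' @export
stroke_drawing <- function(task, strokes = list(),
                           canvas_width = 256L, canvas_height = 256L) {
  task <- match.arg(task, drawing_tasks())
  strokes <- lapply(strokes, function(s) {
    s <- as.matrix(s)
    if (ncol(s) == 2L) s <- cbind(s, 0)   # timestamps optional on input
    if (ncol(s) != 3L) {
      stop("each stroke must have columns x, y, t", call. = FALSE)
    }
    storage.mode(s) <- "double"
    colnames(s) <- c("x", "y", "t")
    rownames(s) <- NULL
    s
  })
  d <- structure(
    list(task = task,
         canvas_width = as.integer(canvas_width),
         canvas_height = as.integer(canvas_height),
         strokes = strokes),
    class = "stroke_drawing"
  )
  validate_stroke_drawing(d)
  d
}

#' @rdname stroke_drawing
#' @export
drawing_tasks <- function() c("cube", "infinity", "clock")

#' Validate a stroke drawing's invariants
#'
#' Checks that all points lie on the canvas, that timestamps within each
#' stroke are non-decreasing, and that no stroke is empty unless the whole
#' drawing is empty.
#'
#' @param d A [stroke_drawing()].
#' @return `d`, invisibly; errors if any invariant fails.
#' @export
validate_stroke_drawing <- function(d) {
  stopifnot(inherits(d, "stroke_drawing"))
  if (d$canvas_width < 1L || d$canvas_height < 1L) {
    stop("canvas dimensions must be positive", call. = FALSE)
  }
  for (i in seq_along(d$strokes)) {
    s <- d$strokes[[i]]
    if (nrow(s) == 0L) {
      stop("stroke ", i, " is empty; empty strokes are only allowed ",
           "as the absence of strokes", call. = FALSE)
    }
    if (any(s[, "x"] < 0 | s[, "x"] >= d$canvas_width |
            s[, "y"] < 0 | s[, "y"] >= d$canvas_height)) {
      stop("stroke ", i, " has points outside the canvas", call. = FALSE)
    }
    if (is.unsorted(s[, "t"])) {
      stop("stroke ", i, " has decreasing timestamps", call. = FALSE)
    }
  }
  invisible(d)
}

#' @export
print.stroke_drawing <- function(x, ...) {
  npts <- sum(vapply(x$strokes, nrow, integer(1)))
  cat(sprintf("<stroke_drawing> task=%s canvas=%dx%d strokes=%d points=%d\n",
              x$task, x$canvas_width, x$canvas_height,
              length(x$strokes), npts))
  invisible(x)
}

#' Serialize a drawing to its JSON stroke format
#'
#' Writes the one-drawing-per-file interchange format:
#' `{"task": ..., "canvas": {"w": ..., "h": ...}, "strokes": [[[x,y,t],...],...]}`.
#' The round trip through [read_drawing()] is lossless.
#'
#' @param drawing A valid [stroke_drawing()].
#' @param path File path to write to.
#' @return `path`, invisibly.
#' @export
write_drawing <- function(drawing, path) {
  validate_stroke_drawing(drawing)
  rec <- list(
    task = drawing$task,
    canvas = list(w = drawing$canvas_width, h = drawing$canvas_height),
    strokes = lapply(drawing$strokes, function(s) {
      lapply(seq_len(nrow(s)), function(i) unname(s[i, ]))
    })
  )
  json <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  ok <- tryCatch({ writeLines(json, path); TRUE },
                 error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("cannot write drawing to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

#' Read a drawing from its JSON stroke format
#'
#' @param path File written by [write_drawing()] (or any conforming record).
#' @return A [stroke_drawing()].
#' @export
read_drawing <- function(path) {
  rec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("task", "canvas", "strokes")) {
    if (is.null(rec[[key]])) {
      stop("drawing record is missing required key '", key, "'",
           call. = FALSE)
    }
  }
  for (key in c("w", "h")) {
    if (is.null(rec$canvas[[key]])) {
      stop("drawing record is missing required key 'canvas.", key, "'",
           call. = FALSE)
    }
  }
  strokes <- lapply(rec$strokes, function(s) {
    m <- do.call(rbind, lapply(s, function(p) as.numeric(unlist(p))))
    colnames(m) <- c("x", "y", "t")
    m
  })
  stroke_drawing(rec$task, strokes,
                 canvas_width = rec$canvas$w, canvas_height = rec$canvas$h)
}

#' @method all.equal stroke_drawing
#' @export
all.equal.stroke_drawing <- function(target, current, ...) {
  if (!inherits(current, "stroke_drawing")) return("not a stroke_drawing")
  all.equal(unclass(target), unclass(current), ...)
}
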