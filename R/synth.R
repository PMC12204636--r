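#' Parametric impairment-like distortions for synthetic drawings
#'
#' Controls how far a generated drawing departs from its canonical template.
#' Zero everywhere reproduces the template exactly; large values produce the
#' kinds of errors impaired patients make: displaced vertices, missing
#' strokes, wavering lines, open curves, misplaced or missing clock numerals,
#' and wrong or absent clock hands.
#'
#' @param vertex_jitter_sd SD (px) of Gaussian displacement of the template's
#'   defining vertices/centers.
#' @param stroke_drop_prob Probability each stroke is omitted.
#' @param wobble_amplitude Amplitude (px) of sinusoidal perpendicular wobble
#'   along each stroke.
#' @param wobble_frequency Wobble cycles per stroke.
#' @param clock_hand_error `"none"`, `"wrong-time"` (hands rotated well away
#'   from ten past five) or `"missing-hand"`.
#' @param clock_numeral_errors Number of numerals (0-12) removed or displaced
#'   off their canonical position.
#' @param closure_gap Gap (px) opened at stroke ends (shrinks cube edges,
#'   opens closed curves).
#' @return An object of class `distortion_spec`.
#' @export
distortion_spec <- function(vertex_jitter_sd = 0, stroke_drop_prob = 0,
                            wobble_amplitude = 0, wobble_frequency = 1,
                            clock_hand_error = c("none", "wrong-time",
                                                 "missing-hand"),
                            clock_numeral_errors = 0L, closure_gap = 0) {
  clock_hand_error <- match.arg(clock_hand_error)
  if (stroke_drop_prob < 0 || stroke_drop_prob > 1) {
    stop("stroke_drop_prob must be in [0, 1]", call. = FALSE)
  }
  if (vertex_jitter_sd < 0 || wobble_amplitude < 0 || closure_gap < 0) {
    stop("jitter, wobble and gap must be >= 0", call. = FALSE)
  }
  clock_numeral_errors <- as.integer(clock_numeral_errors)
  if (clock_numeral_errors < 0L || clock_numeral_errors > 12L) {
    stop("clock_numeral_errors must be in 0..12", call. = FALSE)
  }
  structure(list(vertex_jitter_sd = vertex_jitter_sd,
                 stroke_drop_prob = stroke_drop_prob,
                 wobble_amplitude = wobble_amplitude,
                 wobble_frequency = wobble_frequency,
                 clock_hand_error = clock_hand_error,
                 clock_numeral_errors = clock_numeral_errors,
                 closure_gap = closure_gap),
            class = "distortion_spec")
}

#' Geometric correctness thresholds of the synthetic generator
#'
#' The generator-side rubric: a synthetic drawing is labeled correct exactly
#' when it passes the geometric checks below ([drawing_is_correct()]). The
#' constants are documented here and deliberately loose relative to the
#' correct-cell distortions and tight relative to the incorrect-cell ones.
#'
#' @return Named list of tolerances: `cube_endpoint_tol` (px, stroke
#'   endpoints to canonical cube vertices), `cube_chord_tol` (px, max
#'   perpendicular bowing of an edge), `closure_tol` (px, endpoint gap at
#'   which a closed curve counts as open), `numeral_angle_tol` /
#'   `hand_angle_tol` (degrees), `circle_radius_sd_tol` (px).
#' @export
synth_rubric <- function() {
  list(cube_endpoint_tol = 10, cube_chord_tol = 6,
       closure_tol = 10, numeral_angle_tol = 12,
       hand_angle_tol = 20, circle_radius_sd_tol = 10)
}

synth_canvas <- function() 256L

# ---- canonical templates ---------------------------------------------------

cube_template <- function() {
  f <- rbind(c(70, 100), c(170, 100), c(170, 200), c(70, 200))
  b <- sweep(f, 2, c(46, -46), `+`)
  vertices <- rbind(f, b)                       # 1:4 front, 5:8 back
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1),
                 c(5, 6), c(6, 7), c(7, 8), c(8, 5),
                 c(1, 5), c(2, 6), c(3, 7), c(4, 8))
  list(vertices = vertices, edges = edges)
}

# 91 samples: the self-crossing at t = pi/2 falls mid-segment, never on a
# vertex, so the polyline crossing test sees a proper intersection
lemniscate_points <- function(center, a, npts = 91L) {
  t <- seq(0, 2 * pi, length.out = npts)
  d <- 1 + sin(t)^2
  cbind(x = center[1] + a * cos(t) / d,
        y = center[2] + a * sin(t) * cos(t) / d)
}

infinity_template <- function() {
  list(centers = rbind(c(98, 128), c(158, 128)), a = 60)
}

clock_template <- function() {
  list(center = c(128, 128), radius = 92, numeral_radius = 74,
       glyph_radius = 5, hour_angle = 155, hour_len = 42,
       minute_angle = 60, minute_len = 66)
}

# clock-face direction for an angle measured clockwise from 12 (y down)
clock_dir <- function(deg) {
  th <- deg * pi / 180
  c(sin(th), -cos(th))
}

# ---- stroke construction helpers ------------------------------------------

# straight polyline a -> b with sinusoidal perpendicular wobble and optional
# end gaps; returns npts x 2 matrix
wobbly_segment <- function(a, b, npts, amp, freq, phase, gap) {
  dirv <- b - a
  len <- sqrt(sum(dirv^2))
  if (gap > 0 && len > 0) {
    g <- min(gap / 2, 0.45 * len)
    u <- dirv / len
    a <- a + u * g
    b <- b - u * g
    dirv <- b - a
    len <- sqrt(sum(dirv^2))
  }
  u <- seq(0, 1, length.out = npts)
  pts <- cbind(a[1] + u * dirv[1], a[2] + u * dirv[2])
  if (amp > 0 && len > 0) {
    nrm <- c(-dirv[2], dirv[1]) / len
    w <- amp * sin(2 * pi * freq * u + phase) * sin(pi * u) # pinned ends
    pts <- pts + cbind(w * nrm[1], w * nrm[2])
  }
  pts
}

# radial wobble for closed curves around their centroid
wobble_closed <- function(pts, amp, freq, phase) {
  if (amp <= 0) return(pts)
  ctr <- colMeans(pts)
  dx <- pts[, 1] - ctr[1]; dy <- pts[, 2] - ctr[2]
  r <- sqrt(dx^2 + dy^2)
  r[r == 0] <- 1
  u <- seq(0, 1, length.out = nrow(pts))
  w <- amp * sin(2 * pi * freq * u + phase)
  pts + cbind(w * dx / r, w * dy / r)
}

# open a closed polyline: trim points from both ends until the endpoint
# chord reaches `gap` (at most 40% of the points are removed)
open_curve <- function(pts, gap) {
  if (gap <= 0) return(pts)
  n <- nrow(pts)
  max_trim <- floor(0.2 * n)
  for (k in 0:max_trim) {
    cur <- pts[(1 + k):(n - k), , drop = FALSE]
    if (sqrt(sum((cur[1, ] - cur[nrow(cur), ])^2)) >= gap) return(cur)
  }
  pts[(1 + max_trim):(n - max_trim), , drop = FALSE]
}

clamp_canvas <- function(pts, canvas) {
  pts[, 1] <- pmin(pmax(pts[, 1], 0), canvas - 0.001)
  pts[, 2] <- pmin(pmax(pts[, 2], 0), canvas - 0.001)
  pts
}

# attach synthetic timestamps (2 ms per px of path, 150 ms between strokes)
# and assemble the drawing
assemble_drawing <- function(task, point_sets, canvas) {
  t0 <- 0
  strokes <- list()
  for (pts in point_sets) {
    pts <- clamp_canvas(pts, canvas)
    seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                           pts[-nrow(pts), , drop = FALSE])^2))
    tt <- t0 + c(0, cumsum(seg)) * 2
    strokes[[length(strokes) + 1L]] <- cbind(x = pts[, 1], y = pts[, 2],
                                             t = tt)
    t0 <- max(tt) + 150
  }
  stroke_drawing(task, strokes, canvas_width = canvas, canvas_height = canvas)
}

keep_strokes <- function(point_sets, drop_prob) {
  if (drop_prob <= 0) return(point_sets)
  keep <- stats::runif(length(point_sets)) >= drop_prob
  point_sets[keep]
}

# ---- generators ------------------------------------------------------------

#' Generate a synthetic cube-copy drawing
#'
#' The canonical template is a 12-edge wireframe cube in oblique projection
#' (a front square plus a depth-offset back square and four connectors) on a
#' 256 x 256 canvas, perturbed according to the distortion spec.
#' Deterministic given `seed`.
#'
#' @param distortion A [distortion_spec()].
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @return A [stroke_drawing()] with task `"cube"`.
#' @export
generate_cube <- function(distortion = distortion_spec(), seed = NULL) {
  stopifnot(inherits(distortion, "distortion_spec"))
  if (!is.null(seed)) set.seed(seed)
  canvas <- synth_canvas()
  tpl <- cube_template()
  v <- tpl$vertices
  if (distortion$vertex_jitter_sd > 0) {
    v <- v + matrix(stats::rnorm(length(v), 0, distortion$vertex_jitter_sd),
                    ncol = 2)
  }
  phases <- stats::runif(nrow(tpl$edges), 0, 2 * pi)
  sets <- lapply(seq_len(nrow(tpl$edges)), function(i) {
    e <- tpl$edges[i, ]
    wobbly_segment(v[e[1], ], v[e[2], ], npts = 12L,
                   amp = distortion$wobble_amplitude,
                   freq = distortion$wobble_frequency,
                   phase = phases[i], gap = distortion$closure_gap)
  })
  sets <- keep_strokes(sets, distortion$stroke_drop_prob)
  assemble_drawing("cube", sets, canvas)
}

#' Generate a synthetic overlapping-infinities drawing
#'
#' The template is two overlapping figure-eight (lemniscate) curves sampled
#' as closed polylines whose spans intersect. `closure_gap` opens the curves;
#' jitter displaces their centers. Deterministic given `seed`.
#'
#' @inheritParams generate_cube
#' @return A [stroke_drawing()] with task `"infinity"`.
#' @export
generate_infinity <- function(distortion = distortion_spec(), seed = NULL) {
  stopifnot(inherits(distortion, "distortion_spec"))
  if (!is.null(seed)) set.seed(seed)
  canvas <- synth_canvas()
  tpl <- infinity_template()
  centers <- tpl$centers
  if (distortion$vertex_jitter_sd > 0) {
    centers <- centers +
      matrix(stats::rnorm(length(centers), 0, distortion$vertex_jitter_sd),
             ncol = 2)
  }
  phases <- stats::runif(2, 0, 2 * pi)
  sets <- lapply(1:2, function(i) {
    pts <- lemniscate_points(centers[i, ], tpl$a)
    pts <- wobble_closed(pts, distortion$wobble_amplitude,
                         distortion$wobble_frequency, phases[i])
    open_curve(pts, distortion$closure_gap)
  })
  sets <- keep_strokes(sets, distortion$stroke_drop_prob)
  assemble_drawing("infinity", sets, canvas)
}

#' Generate a synthetic clock drawing (ten past five)
#'
#' The template is a circular face, numerals 1-12 as small glyph strokes at
#' their canonical angular positions (numeral k at k * 30 degrees clockwise
#' from 12), an hour hand toward the 5:10 position (155 degrees) and a
#' minute hand toward 2 (60 degrees), the hour hand shorter. Distortions
#' relocate or remove numerals and alter or remove hands. Deterministic
#' given `seed`.
#'
#' @inheritParams generate_cube
#' @return A [stroke_drawing()] with task `"clock"`.
#' @export
generate_clock <- function(distortion = distortion_spec(), seed = NULL) {
  stopifnot(inherits(distortion, "distortion_spec"))
  if (!is.null(seed)) set.seed(seed)
  canvas <- synth_canvas()
  tpl <- clock_template()
  ctr <- tpl$center
  if (distortion$vertex_jitter_sd > 0) {
    ctr <- ctr + stats::rnorm(2, 0, distortion$vertex_jitter_sd / 2)
  }
  # face
  th <- seq(0, 2 * pi, length.out = 121L)
  face <- cbind(ctr[1] + tpl$radius * sin(th), ctr[2] - tpl$radius * cos(th))
  face <- wobble_closed(face, distortion$wobble_amplitude,
                        distortion$wobble_frequency,
                        stats::runif(1, 0, 2 * pi))
  face <- open_curve(face, distortion$closure_gap)
  sets <- list(face)
  # numerals: small glyph clusters; errors displace (>= 25 deg) or remove
  err_idx <- integer(0)
  if (distortion$clock_numeral_errors > 0L) {
    err_idx <- sample.int(12L, distortion$clock_numeral_errors)
  }
  removed <- stats::runif(12) < 0.5
  err_shift <- sample(c(-1, 1), 12, replace = TRUE) * stats::runif(12, 25, 90)
  for (k in 1:12) {
    ang <- k * 30
    if (k %in% err_idx) {
      if (removed[k]) next
      ang <- ang + err_shift[k]
    }
    gc <- ctr + tpl$numeral_radius * clock_dir(ang)
    if (distortion$vertex_jitter_sd > 0) {
      gc <- gc + stats::rnorm(2, 0, distortion$vertex_jitter_sd)
    }
    gt <- seq(0, 2 * pi, length.out = 9L)
    sets[[length(sets) + 1L]] <-
      cbind(gc[1] + tpl$glyph_radius * cos(gt),
            gc[2] + tpl$glyph_radius * sin(gt))
  }
  # hands
  hour_ang <- tpl$hour_angle
  minute_ang <- tpl$minute_angle
  hand_rot <- sample(c(-1, 1), 2, replace = TRUE) *
    stats::runif(2, c(60, 45), 180)
  drop_which <- sample.int(2L, 1L)
  if (distortion$clock_hand_error == "wrong-time") {
    hour_ang <- hour_ang + hand_rot[1]
    minute_ang <- minute_ang + hand_rot[2]
  }
  if (distortion$vertex_jitter_sd > 0) {
    hour_ang <- hour_ang + stats::rnorm(1, 0, distortion$vertex_jitter_sd)
    minute_ang <- minute_ang + stats::rnorm(1, 0, distortion$vertex_jitter_sd)
  }
  hands <- list(
    hour = rbind(ctr, ctr + tpl$hour_len * clock_dir(hour_ang)),
    minute = rbind(ctr, ctr + tpl$minute_len * clock_dir(minute_ang))
  )
  if (distortion$clock_hand_error == "missing-hand") {
    hands[[drop_which]] <- NULL
  }
  phases <- stats::runif(2, 0, 2 * pi)
  for (i in seq_along(hands)) {
    h <- hands[[i]]
    sets[[length(sets) + 1L]] <-
      wobbly_segment(h[1, ], h[2, ], npts = 10L,
                     amp = distortion$wobble_amplitude,
                     freq = distortion$wobble_frequency,
                     phase = phases[i], gap = 0)
  }
  sets <- keep_strokes(sets, distortion$stroke_drop_prob)
  assemble_drawing("clock", sets, canvas)
}

#' @rdname generate_cube
#' @param task Which generator to dispatch to.
#' @export
generate_drawing <- function(task, distortion = distortion_spec(),
                             seed = NULL) {
  switch(match.arg(task, drawing_tasks()),
         cube = generate_cube(distortion, seed),
         infinity = generate_infinity(distortion, seed),
         clock = generate_clock(distortion, seed))
}

# ---- geometric correctness checks ------------------------------------------

ang_diff <- function(a, b) {
  d <- abs((a - b) %% 360)
  pmin(d, 360 - d)
}

# clock-face angle (deg clockwise from 12) of point p about center ctr
clock_angle <- function(p, ctr) {
  (atan2(p[1] - ctr[1], -(p[2] - ctr[2])) * 180 / pi) %% 360
}

# do any two segments of polylines P and Q properly intersect?
# (skip_adjacent: treat P and Q as the same curve and ignore neighbours)
polylines_intersect <- function(P, Q, same_curve = FALSE) {
  cross2 <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  np <- nrow(P) - 1L; nq <- nrow(Q) - 1L
  for (i in seq_len(np)) {
    jmax <- nq
    jmin <- if (same_curve) i + 2L else 1L
    if (jmin > jmax) next
    for (j in jmin:jmax) {
      if (same_curve && i == 1L && j == np) next  # closed-curve wraparound
      d1 <- cross2(Q[j, 1], Q[j, 2], Q[j + 1, 1], Q[j + 1, 2], P[i, 1], P[i, 2])
      d2 <- cross2(Q[j, 1], Q[j, 2], Q[j + 1, 1], Q[j + 1, 2],
                   P[i + 1, 1], P[i + 1, 2])
      d3 <- cross2(P[i, 1], P[i, 2], P[i + 1, 1], P[i + 1, 2], Q[j, 1], Q[j, 2])
      d4 <- cross2(P[i, 1], P[i, 2], P[i + 1, 1], P[i + 1, 2],
                   Q[j + 1, 1], Q[j + 1, 2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

stroke_xy <- function(s) s[, c("x", "y"), drop = FALSE]

check_cube <- function(d, tol = synth_rubric()) {
  if (length(d$strokes) != 12L) return(FALSE)
  tpl <- cube_template()
  taken <- rep(FALSE, 12L)
  for (s in d$strokes) {
    pts <- stroke_xy(s)
    p0 <- pts[1, ]; p1 <- pts[nrow(pts), ]
    best <- Inf; best_e <- NA_integer_
    for (e in 1:12) {
      a <- tpl$vertices[tpl$edges[e, 1], ]
      b <- tpl$vertices[tpl$edges[e, 2], ]
      cost <- min(max(sqrt(sum((p0 - a)^2)), sqrt(sum((p1 - b)^2))),
                  max(sqrt(sum((p0 - b)^2)), sqrt(sum((p1 - a)^2))))
      if (cost < best) { best <- cost; best_e <- e }
    }
    if (best > tol$cube_endpoint_tol || taken[best_e]) return(FALSE)
    taken[best_e] <- TRUE
    # bowing: max perpendicular deviation from the chord
    chord <- p1 - p0
    len <- sqrt(sum(chord^2))
    if (len < 1) return(FALSE)
    perp <- abs((pts[, 1] - p0[1]) * chord[2] -
                  (pts[, 2] - p0[2]) * chord[1]) / len
    if (max(perp) > tol$cube_chord_tol) return(FALSE)
  }
  all(taken)
}

check_infinity <- function(d, tol = synth_rubric()) {
  if (length(d$strokes) != 2L) return(FALSE)
  P <- stroke_xy(d$strokes[[1]])
  Q <- stroke_xy(d$strokes[[2]])
  for (pts in list(P, Q)) {
    if (nrow(pts) < 8L) return(FALSE)
    gap <- sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2))
    if (gap > tol$closure_tol) return(FALSE)
    if (diff(range(pts[, 1])) < 40) return(FALSE)
    if (!polylines_intersect(pts, pts, same_curve = TRUE)) return(FALSE)
  }
  polylines_intersect(P, Q)
}

check_clock <- function(d, tol = synth_rubric()) {
  if (length(d$strokes) < 3L) return(FALSE)
  sizes <- vapply(d$strokes, function(s) {
    pts <- stroke_xy(s)
    sqrt(diff(range(pts[, 1]))^2 + diff(range(pts[, 2]))^2)
  }, numeric(1))
  face_i <- which.max(sizes)
  face <- stroke_xy(d$strokes[[face_i]])
  ctr <- colMeans(face)
  r <- sqrt((face[, 1] - ctr[1])^2 + (face[, 2] - ctr[2])^2)
  if (mean(r) < 60 || mean(r) > 120) return(FALSE)
  if (stats::sd(r) > tol$circle_radius_sd_tol) return(FALSE)
  gap <- sqrt(sum((face[1, ] - face[nrow(face), ])^2))
  if (gap > tol$closure_tol) return(FALSE)
  # split remaining strokes into hands (anchored at center) and numerals
  rest <- setdiff(seq_along(d$strokes), face_i)
  hands <- list(); numerals <- list()
  for (i in rest) {
    pts <- stroke_xy(d$strokes[[i]])
    d_ends <- sqrt(pmin(sum((pts[1, ] - ctr)^2),
                        sum((pts[nrow(pts), ] - ctr)^2)))
    reach <- max(sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2))
    if (d_ends < 18 && reach > 25) hands[[length(hands) + 1L]] <- pts
    else numerals[[length(numerals) + 1L]] <- pts
  }
  if (length(hands) != 2L || length(numerals) != 12L) return(FALSE)
  reach <- vapply(hands, function(p) {
    max(sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2))
  }, numeric(1))
  hour <- hands[[which.min(reach)]]
  minute <- hands[[which.max(reach)]]
  if (reach[which.min(reach)] >= reach[which.max(reach)]) return(FALSE)
  tip_ang <- function(p) {
    tip <- p[which.max(sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)), ]
    clock_angle(tip, ctr)
  }
  if (ang_diff(tip_ang(hour), clock_template()$hour_angle) >
        tol$hand_angle_tol) return(FALSE)
  if (ang_diff(tip_ang(minute), clock_template()$minute_angle) >
        tol$hand_angle_tol) return(FALSE)
  # numerals: all 12 canonical positions covered, one each, in a radial band
  ang <- vapply(numerals, function(p) clock_angle(colMeans(p), ctr),
                numeric(1))
  rad <- vapply(numerals, function(p) {
    sqrt(sum((colMeans(p) - ctr)^2))
  }, numeric(1))
  if (any(rad < 0.45 * mean(r) | rad > 0.95 * mean(r))) return(FALSE)
  assigned <- rep(FALSE, 12L)
  for (i in seq_along(ang)) {
    k <- which(ang_diff(ang[i], (1:12) * 30) <= tol$numeral_angle_tol)
    k <- k[!assigned[k]]
    if (!length(k)) return(FALSE)
    assigned[k[1]] <- TRUE
  }
  all(assigned)
}

#' Generator-side correctness of a synthetic drawing
#'
#' Applies the geometric correctness checks of the generator's rubric
#' ([synth_rubric()]): a cube needs all 12 edges present near their canonical
#' vertices without excessive bowing; the infinities need two closed,
#' self-crossing, mutually overlapping figure-eights; a clock needs a closed
#' round face, all 12 numerals at their canonical angular positions, and two
#' center-anchored hands at ten past five with the hour hand shorter.
#' All-or-nothing per task, mirroring the rubric's single point award.
#'
#' @param drawing A [stroke_drawing()].
#' @return `TRUE` if the drawing passes its task's checks.
#' @export
drawing_is_correct <- function(drawing) {
  stopifnot(inherits(drawing, "stroke_drawing"))
  switch(drawing$task,
         cube = check_cube(drawing),
         infinity = check_infinity(drawing),
         clock = check_clock(drawing))
}

# ---- labeled dataset generation -------------------------------------------

sample_correct_distortion <- function() {
  distortion_spec(vertex_jitter_sd = stats::runif(1, 0.5, 2),
                  wobble_amplitude = stats::runif(1, 0.3, 1.5),
                  wobble_frequency = sample(1:3, 1))
}

sample_incorrect_distortion <- function(task) {
  mode <- switch(task,
                 cube = sample(c("drop", "jitter", "wobble"), 1),
                 infinity = sample(c("open", "drop", "jitter"), 1),
                 clock = sample(c("missing-hand", "wrong-time",
                                  "numerals", "jitter"), 1))
  base_jitter <- stats::runif(1, 0.5, 2)
  switch(mode,
    drop = distortion_spec(vertex_jitter_sd = base_jitter,
                           stroke_drop_prob = stats::runif(1, 0.25, 0.6)),
    jitter = distortion_spec(vertex_jitter_sd = stats::runif(1, 14, 24)),
    wobble = distortion_spec(vertex_jitter_sd = base_jitter,
                             wobble_amplitude = stats::runif(1, 9, 16),
                             wobble_frequency = sample(2:4, 1)),
    open = distortion_spec(vertex_jitter_sd = base_jitter,
                           closure_gap = stats::runif(1, 30, 70)),
    `missing-hand` = distortion_spec(vertex_jitter_sd = base_jitter,
                                     clock_hand_error = "missing-hand"),
    `wrong-time` = distortion_spec(vertex_jitter_sd = base_jitter,
                                   clock_hand_error = "wrong-time"),
    numerals = distortion_spec(vertex_jitter_sd = base_jitter,
                               clock_numeral_errors = sample(4:12, 1)))
}

#' Generate a labeled synthetic training set
#'
#' For each task, draws `n_per_cell` drawings of which
#' `round(correct_fraction * n_per_cell)` are correct (low distortion) and
#' the rest incorrect (one of the task's failure modes beyond the rubric
#' thresholds). Every label is verified against [drawing_is_correct()]:
#' candidates whose geometric label disagrees with the requested one are
#' regenerated under the next derived seed, so label soundness holds by
#' construction. Deterministic given `seed`.
#'
#' @param n_per_cell Drawings per task (>= 1).
#' @param correct_fraction Fraction of each task's drawings labeled correct.
#' @param seed Integer seed for the whole dataset.
#' @param tasks Tasks to include (default all three).
#' @return A list of class `synth_dataset`; each element has `drawing` (a
#'   [stroke_drawing()]) and `label` (list with `task`, `correct`,
#'   `distortion`, `seed`).
#' @export
generate_labeled_dataset <- function(n_per_cell, correct_fraction = 0.5,
                                     seed = 1L, tasks = drawing_tasks()) {
  if (n_per_cell < 1L) stop("n_per_cell must be >= 1", call. = FALSE)
  if (correct_fraction < 0 || correct_fraction > 1) {
    stop("correct_fraction must be in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  n_correct <- round(correct_fraction * n_per_cell)
  base_seeds <- sample.int(2147480000L, length(tasks) * n_per_cell)
  out <- vector("list", length(tasks) * n_per_cell)
  item <- 0L
  for (task in tasks) {
    for (i in seq_len(n_per_cell)) {
      item <- item + 1L
      want_correct <- i <= n_correct
      for (attempt in 0:49) {
        s <- (base_seeds[item] + 7919L * attempt) %% 2147483629L + 1L
        set.seed(s)
        dist <- if (want_correct) sample_correct_distortion()
                else sample_incorrect_distortion(task)
        d <- generate_drawing(task, dist, seed = s + 1L)
        if (drawing_is_correct(d) == want_correct) break
        d <- NULL
      }
      if (is.null(d)) {
        stop("could not generate a ", if (want_correct) "correct"
             else "incorrect", " ", task, " drawing in 50 attempts",
             call. = FALSE)
      }
      out[[item]] <- list(drawing = d,
                          label = list(task = task, correct = want_correct,
                                       distortion = dist, seed = s + 1L))
    }
  }
  structure(out, class = "synth_dataset",
            seed = seed, n_per_cell = n_per_cell,
            correct_fraction = correct_fraction)
}

#' Manifest of a synthetic dataset
#'
#' @param dataset A [generate_labeled_dataset()] result.
#' @return Data.frame with columns `file`, `task`, `correct`, `seed`.
#' @export
dataset_manifest <- function(dataset) {
  stopifnot(inherits(dataset, "synth_dataset"))
  data.frame(
    file = sprintf("drawing_%04d.json", seq_along(dataset)),
    task = vapply(dataset, function(x) x$label$task, character(1)),
    correct = vapply(dataset, function(x) x$label$correct, logical(1)),
    seed = vapply(dataset, function(x) x$label$seed, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Write a synthetic dataset to disk
#'
#' One stroke-JSON file per drawing plus a `manifest.csv`.
#'
#' @param dataset A [generate_labeled_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- dataset_manifest(dataset)
  for (i in seq_along(dataset)) {
    write_drawing(dataset[[i]]$drawing, file.path(dir, man$file[i]))
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
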