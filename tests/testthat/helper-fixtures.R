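# shared fixtures, all built in code

# one horizontal stroke on a small canvas
line_drawing <- function(x0 = 2, x1 = 8, y = 5, canvas = 16) {
  stroke_drawing("cube",
                 list(cbind(x = c(x0, x1), y = c(y, y), t = c(0, 100))),
                 canvas_width = canvas, canvas_height = canvas)
}

# a tiny network that trains in seconds
tiny_net_config <- function(classes = sketch_classes(), seed = 9L) {
  net_config(input_size = 16L, class_names = classes, stem_channels = 4L,
             fire_specs = list(c(2L, 4L, 4L)), pool_after = 1L, seed = seed)
}

# cohort with perfectly separating task performance
degenerate_cohort_spec <- function(n = 40L) {
  cohort_spec(n = n, p_incorrect = matrix(
    c(0, 0, 0, 1, 1, 1), nrow = 2, byrow = TRUE,
    dimnames = list(c("intact", "impaired"), c("cube", "infinity", "clock"))))
}

# brute-force Mann-Whitney concordance (ties count 1/2), low score = positive
mw_concordance <- function(scores, truth, positive = "impaired") {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a < b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
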