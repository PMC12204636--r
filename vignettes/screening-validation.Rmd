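---
title: "Validating a drawing-based cognitive screen: models, rubric and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a drawing-based cognitive screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roca)
```

## The screening problem

Paper-based cognitive screens (ACE-3, MoCA) are well validated but scale
poorly. A remote, self-administered drawing battery can emulate the drawing
items of those tests: the patient copies a wireframe cube, copies
overlapping infinities, and draws a clock face showing ten past five. Each
drawing is judged correct or incorrect by a convolutional sketch
classifier, and points are awarded all-or-nothing: 2 for the cube, 1 for
the infinities, 5 for the clock, a maximum total of 8. A patient screens
*positive* (possibly impaired, refer on) when the total falls at or below
a threshold; the instrument is a rule-out screen, so sensitivity and
negative predictive value (NPV) are the metrics that matter.

This package implements the battery's data model, the classifier, the
rubric, and — the statistical core — the complete validation framework
such a screen needs: chance baselines, ROC/AUC with Youden threshold
selection, bootstrap inference, threshold sweeps, covariate regressions,
and AUC-based sample-size planning. Because no patient data ship with the
package, a synthetic drawing generator and a cohort simulator stand in for
them; both are first-class, tested components.

## Drawing model

A drawing is an ordered list of pen strokes, each an ordered list of
`(x, y, t)` points on a pixel canvas (origin top-left, y down, 0-based).
Timestamps are carried for provenance but never scored: the battery grades
static drawings. Serialization is a one-drawing-per-file JSON format that
round-trips losslessly; rasters are exchanged as grayscale PNG.

Rasterization draws strokes as connected segments with a square pen tip
(default 2 px on a 256 px canvas). Preprocessing finds the ink bounding
box, centers it on a square grid (default 96 px) scaled to fit inside a
10% margin with aspect ratio preserved, using bilinear interpolation. Two
numerical choices matter here:

* The bounding box is detected at **half intensity** (`> 0.5`), not at
  any nonzero ink. This makes the box insensitive to the faint halo that
  bilinear resampling spreads around strokes, so re-preprocessing an
  already-preprocessed raster is numerically stable (the package tests
  assert a near-fixed-point, not bit equality, since a non-integer scale
  always resamples).
* Output is invariant under integer translation of the input ink — the
  box moves with the ink — which the test suite checks to floating-point
  precision.

The canvas, resolution and preprocessing constants are artifact decisions;
nothing in the source battery prescribes them. 96 px keeps CPU training
cheap while a 2 px pen survives the 256-to-96 downsampling.

## Synthetic drawings and their rubric

The generator draws canonical templates and perturbs them with
impairment-like distortions:

* **Cube** — 12 edges of an oblique-projection wireframe (front square,
  depth-offset back square, 4 connectors). Zero distortion reproduces the
  template exactly.
* **Infinities** — two overlapping lemniscates sampled as closed
  polylines. The sampling count (91) is chosen so the self-crossing falls
  mid-segment, never on a vertex, keeping the polyline intersection test
  well-posed.
* **Clock** — circular face, numerals 1-12 as small glyph clusters at
  their canonical angles (numeral k at k·30° clockwise from 12), an hour
  hand toward 5:10 (155°) and a longer minute hand toward 2 (60°).

Distortions: Gaussian jitter of defining vertices/centers, per-stroke drop
probability, sinusoidal wobble, endpoint gaps that open closed curves, and
clock-specific errors (wrong-time or missing hands, numerals removed or
displaced by at least 25°).

Ground-truth labels come from generator-side geometric checks
(`drawing_is_correct()`), mirroring the established scoring guidelines
that the original battery's human raters used but which are not published
in reproducible detail. The thresholds are documented constants
(`synth_rubric()`): 10 px endpoint tolerance and 6 px bowing for the cube,
10 px closure tolerance, 12° numeral and 20° hand angular tolerance.
Correctness is all-or-nothing per task, matching the rubric's single point
award. `generate_labeled_dataset()` verifies every label against these
checks and regenerates disagreeing candidates under the next derived seed,
so label soundness holds by construction; the correct-cell distortions
(jitter ≤ 2 px, wobble ≤ 1.5 px) sit far below the thresholds and the
incorrect-cell failure modes sit far above them, which is what makes the
classes learnable at desk scale.

What the generator does *not* emulate: real handwriting style, pen
pressure, hesitation and self-correction, device heterogeneity, or the
drawing phenotypes of specific dementia etiologies. A classifier that
separates these synthetic classes demonstrates that the pipeline — stroke
capture, rasterization, training, condensation, scoring — works end to
end; it says nothing about accuracy on patient drawings.

## The classifier

The sketch classifier is a compact fire-module convolutional network
written directly in R on dense matrix products (im2col + BLAS): a strided
3×3 stem, fire modules (1×1 squeeze feeding parallel 1×1 and 3×3 expands,
concatenated), 2×2 max pooling, a 1×1 class head, global average pooling
and softmax. The default stack (8 stem channels; fire specs 4/8/8,
8/16/16, 8/16/16; pooling after the first two) has about 20k parameters —
deliberately small so that 15 epochs on 600 drawings finish in minutes on
one CPU. The full-size architecture in this family is expressible through
`net_config()` if wanted.

The network is multiclass (task × correctness, 6 classes by default);
predictions are condensed to correct/incorrect per task, and the condensed
judgment is what the rubric scores. Training is seeded mini-batch Adam
(defaults: 15 epochs, batch 16, learning rate 5e-3, 20% stratified
validation split) minimizing cross-entropy; identical seeds give identical
runs because everything is single-threaded deterministic R. Training from
scratch on synthetic data is the default; a transfer-learning hook accepts
an externally supplied checkpoint (`pretrained_source`), because requiring
a weight download would break a self-contained build. The layer mathematics
is verified in the test suite against a direct-summation convolution oracle
and finite-difference gradients.

## Cohort simulation and its closed-form oracle

A simulated cohort draws cognitive status Bernoulli(prevalence), then task
correctness conditionally independent given status — the simplest
structure consistent with a validation design that reports no inter-task
correlation — and scores the battery. Defaults reproduce the published
cohort's structure: prevalence 17/46 (the tabulated 17 impaired / 29
intact; the running text's 16/30 is selectable instead, but only the 17/29
prior reproduces the printed 63% chance NPV), age 49.1 (SD 15), 52%
female, 78/17/4% secondary/postsecondary/less-than-secondary education,
63% employed, the tabulated ethnicity mix, 76% ACE-3.

The default per-task incorrect rates (intact 0.10/0.15/0.10, impaired
0.55/0.50/0.65) were fixed once, analytically, so that the implied
operating point sits where the published screen operates: P(all correct)
≈ 0.69 for intact (vs 19/29 ≈ 0.66 observed) and ≈ 0.08 for impaired (vs
1/17 ≈ 0.06), giving closed-form sensitivity ≈ 0.92, NPV ≈ 0.94 and AUC ≈
0.89 at the 7/8 cut. Covariates are null by default — they do not touch
the score — so regression specificity is testable; known effects can be
injected for power studies (`covariate_effects`), in which case the score
becomes continuous so the injected effect is exact rather than distorted
by integer rounding.

`closed_form_performance()` enumerates the 8 correctness patterns per
status and computes exact metrics and the exact Mann-Whitney AUC of the
two score distributions. It is the analytic oracle every Monte-Carlo
result must converge to, and the tests check this at n = 10,000 within 3
Monte-Carlo standard errors. A sharp rubric consequence worth noting: the
reachable totals are {0, 1, 2, 3, 5, 6, 7, 8} — a total of 4 cannot occur
under 2/1/5 scoring.

## The statistical engine

**Chance baseline.** A random classifier predicts independently of its
input: cell (i, j) of its expected confusion matrix is the selection
probability q_i times the class prior p_j. Selection probabilities default
to uniform — the only choice under which binary chance sensitivity is 50%
regardless of prevalence — with an empirical-prior option for multiclass
baselines, where the convention is genuinely ambiguous. Two algebraic
consequences anchor the test suite: chance accuracy is exactly 1/2 for
any prior when q is uniform, and chance NPV equals the negative-class
prior for *every* non-degenerate q (the q cancels), which is 29/46 ≈ 63%
under the default cohort prior.

**ROC, AUC, Youden.** The screening score is 0-8 with low scores
indicating impairment, so the ROC sweeps the rule "positive iff score ≤ t"
over all achievable thresholds plus a strictest sentinel. AUC is the
trapezoidal area, identical to the Mann-Whitney concordance with ties
counted ½ (asserted exactly, to 1e-12, over random instances, and against
an independent ROC implementation). The Youden index J = sensitivity +
specificity − 1 picks the operating threshold; ties break toward the
strictest threshold, the conservative choice for a screen.

**Bootstrap.** Percentile bootstrap throughout — the resampling scheme
was specified no further than "with replacement", and percentile intervals
are the assumption-lightest reading. The resampling unit is the patient
for diagnostic statistics and the drawing for drawing-level accuracy;
conventionally 1,000 resamples for drawing-level and 10,000 for
diagnostic-level inference. Resamples on which a statistic is undefined
(e.g. single-class) are redrawn and counted. The p-value against a chance
value c is the fraction of bootstrap statistics ≤ c — "falls at or below
chance", the conservative reading — with the resolution floor 1/n_boot
reported when the count is zero. Zero-denominator metrics yield flagged
`NA`s, never errors, so sweeps over extreme thresholds always complete.

**Threshold semantics.** The published optimal cut "7/8" is read as
*positive iff score ≤ 7*: only a perfect battery screens negative. This is
the only reading consistent with the printed operating-point confusion
matrix (26 predicted positive, 20 predicted negative of 46), and the
direction (low score ⇒ impaired) is forced by the test's design. The
strict alternative (`< 7`) remains selectable. The threshold sweep reports
all thresholds with bootstrap bands and identifies the screening optimum:
the threshold maximizing sensitivity + NPV, undefined metrics excluded,
ties to the strictest.

**AUC is reported twice** — once on the original sample (the point
estimate) and once as the mean over bootstrap resamples — because the two
are distinct quantities and the source analyses distinguish them.

**Sample size.** The Hanley-McNeil variance
V = [A(1−A) + (n₁−1)(Q1−A²) + (n₂−1)(Q2−A²)]/(n₁n₂), with Q1 = A/(2−A)
and Q2 = 2A²/(1+A), drives a per-group sample-size search: the smallest
equal n at which a z-test of AUC = 0.5 against the alternative A attains
the requested power, using the null variance under the null and the
alternative variance under the alternative. Alpha defaults to 0.05
one-sided; both are exposed because published sample-size statements in
this setting routinely omit them. Notably, the claims that motivated the
original recruitment (16+16 at AUC 0.70, 2+2 at 0.90 for 80% power) do
not state alpha or sidedness and are not exactly reproducible under the
standard formulation above (one-sided 0.05 gives 25 per group at AUC
0.70); the package exposes the parameters and documents the discrepancy
rather than tuning to match.

**Covariate regressions.** Ordinary least squares of the score on age,
ethnicity, sex, education, employment, exam type and cognitive status
jointly; plus one model per covariate crossing it with status to test
effect compounding. Categorical covariates use reference-level indicators
with the most frequent level as reference (the source is silent on
encoding; this matches common practice and the cohort's dominant
categories); age is not centered; no multiplicity adjustment is applied
across the interaction series, mirroring the original analysis. Rank
deficiency is an error naming the collinear terms; a constant response is
flagged degenerate with zero slopes rather than fitted.

## Problem sizes and reproducibility

The package's own experiments run at desk scale, chosen so the full test
suite and the acceptance script finish comfortably on one CPU: classifier
training on 600 drawings (100 per task × correctness cell) for 15 epochs
with a 120-drawing fresh holdout; bootstrap coverage checked with 500
outer replications of n = 200 at 1,000 resamples; oracle convergence at
n = 10,000 simulated patients; property suites over 200 random small
instances. Every random operation takes an explicit seed, and the
end-to-end pipeline (`run_pipeline()`) derives all stage seeds from one
master seed, so a rerun of the same configuration reproduces the report
exactly, timestamp aside.

## Known limitations

* Synthetic drawings are geometric perturbations, not handwriting; the
  classifier's measured accuracy is an upper bound on nothing but the
  synthetic task, and transfers to no patient population.
* Conditional independence of task failures given status is an assumption;
  real batteries likely show correlated failures, which would widen the
  score distribution within status and lower the achievable AUC.
* The cohort simulator draws covariates independently of status (unless
  effects are injected), so it cannot represent confounding between, say,
  age and impairment.
* Test-retest stability and longitudinal change are out of scope, as is
  any deployment infrastructure (links, servers, storage).
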