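---
title: "Scoring and validating iVR MCI triage performance indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and validating iVR MCI triage performance indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcitriage)
```

This vignette is the package's account of the science behind its scoring
rules, its statistical battery, and its synthetic cohort generator: what is
modeled, which parameters matter, which choices were genuinely open, and
what the passing test suite does and does not demonstrate.

## The measurement model

A participant completes five virtual mass-casualty scenarios of increasing
difficulty (4 to 18 patients; the bundled rosters reproduce the published
scenario compositions) plus an empty familiarization scenario. Four
objective indicator families and one subjective composite are derived per
participant.

**Triage accuracy.** Each scenario log is a sequence of
`(patient, colour, time)` events. Accuracy is the number of patients whose
final assigned colour equals the roster's ground-truth START colour,
divided by the roster size, then averaged (unweighted) over the five
scenarios, giving a value in $[0, 1]$. Two rules are deliberate choices
where the procedure leaves room: an untriaged patient counts as incorrect
(the denominator is the fixed roster size, so walking away from patients
cannot raise the score), and a re-triaged patient keeps the *last*
assignment, mirroring in-scenario correction. Ground truth in the bundled
rosters is exactly the START classification of each patient's findings;
whether a study team might adjudicate differently is unknowable from the
outside, so roster colours are treated as authoritative.

**Triage speed.** Raw completion time (seconds to the last triage event)
grows with scenario length, so naive averaging over-weights the long
scenarios. Each cell is therefore divided by the cohort mean of its
scenario column before row-wise averaging. The scenario mean *includes*
the participant's own time — the plain reading of "the average of the
scenario" — which makes every standardized column average exactly 1 and
renders the indicator invariant to rescaling all raw times. Values below 1
are faster than the cohort average.

**Visual attention.** Gaze is modeled on a scenario-fixed angular
panorama (yaw/pitch in degrees) rather than by 3-D ray casting; AOIs are
2-D polygons on that plane. Fixations are detected with the
dispersion-threshold algorithm (I-DT): maximal non-overlapping windows
whose dispersion — the larger of the x- and y-range — stays within
`max_dispersion_deg` (default 1°) for at least `min_duration_ms` (default
100 ms). The vendor software used in practice does not publish its
parameters; these defaults are the standard textbook choices and both are
exposed. A fixation belongs to the AOI polygon containing its centroid,
with nested/overlapping polygons resolved in favour of the smallest area;
anything else is background. Background fixations are kept for the
conservation check (category counts plus background equals the total) but
excluded from the indicators. Aggregation follows the two published rules
exactly: DOAF (duration of average fixation) is averaged per scenario and
then across the scenarios *where the category has an AOI*; FC (fixation
count) is summed per scenario and then averaged the same way. A scenario
whose AOI drew no fixations contributes a missing value to DOAF (an
average of nothing is not zero) but a zero to FC (a count of nothing is
zero); the distractor exists only in scenario 3, so its "cross-scenario"
value is the scenario-3 value alone.

**Information-transmission efficiency.** Radio messages are coded against
the four SSSS categories (scene, safety, situation, support), at most one
point each: 0.5 for a scene mention without detail, 1 with detail (street
type or vehicles); 1 for safety, situation and support mentions; 0.3
deducted per error in a category and floored at zero (the published 0–4
range implies no negative category scores). A situation error is a wrong
patient count; in the two most complex scenarios an estimate within ±2 is
tolerated. The tolerance is implemented as an absolute $|\Delta| \le 2$ on
a single extracted integer; phrasings such as ranges are outside the
controlled lexicon. A situation raised without any count is scored as
mentioned with one error (the count was not "stated correctly") — this is
switchable in spirit but fixed as the default because the alternative
(treating it as absent) conflates saying nothing with saying something
vague. The 0–4 total divided by the word count (whitespace tokens,
punctuation-only tokens ignored) is the per-scenario efficiency, averaged
over available scenarios. Incorrect triage colours in the message are
never penalized here, because the accuracy indicator already covers them.

**Subjective composite.** The second self-rating item is a German school
grade (1 best, 6 worst); it is inverted and mapped linearly onto the 1–10
scale of the first item, `10 − 1.8·(grade − 1)`, and the two items are
averaged. The linear map is a reconstruction (the published formula figure
is not machine-readable); it is the unique affine map sending best→10 and
worst→1.

## The validation battery

`run_battery()` executes, in order: winsorization of every indicator at
mean ± 3 SD (bounds from the original vector, one pass — re-running on
already-clamped data recomputes bounds, so the operation is applied once
per analysis); a Levene test per indicator that gates Student vs Welch t
tests; Shapiro–Wilk statistics recorded per group; MANOVAs (Pillai's
trace) across the four AOI categories for DOAF and FC; the three
directional t tests (accuracy, speed, efficiency) with Bonferroni–Holm
correction over exactly that family of three; Spearman correlations of the
knowledge score and of the subjective composite with the indicators; the
centered OLS regression of accuracy on knowledge, age and gender
(−1 female, +1 male) with case-resampling bootstrap percentile intervals;
and standardized Cronbach's α per multi-scenario indicator,
$\alpha = k\bar r / (1 + (k-1)\bar r)$.

Two decisions deserve emphasis. First, the three indicator hypotheses are
*directional* (experienced responders are more accurate, faster, more
efficient), and the published raw-p/adjusted-p pattern is consistent with
one-tailed tests, so `tail = "one"` is the default; `battery_config()`
switches to two-tailed. Second, the Holm family is exactly the three
indicator tests — the knowledge-score comparison and the exploratory
correlations are outside the family, as in the source analysis plan.
Missing data are handled per measure: a participant missing one indicator
is excluded from that indicator's test only, so per-test sample sizes
differ by design.

## What the synthetic generator emulates

`generator_config()` defaults encode the study conditions: 39 MFR and 37
non-MFR participants; knowledge scores drawn from truncated normals
(13.46 ± 2.73 vs 10.89 ± 3.70 points) and realized *exactly* as answer
vectors to the bundled 20-item test; per-patient triage correctness as a
Bernoulli draw with a participant-level probability
$p_i = p_g + 0.017\,(K_i - \mu_g) + e_i$ clamped to $[0.02, 0.995]$, with
group levels 0.84/0.77 and residual SDs 0.087/0.155 chosen so the scored
accuracy SDs match the published 0.12/0.18; wrong colours drawn from
adjacent severity levels (weights 0.80/0.15/0.05 by distance — no
confusion structure is published, and adjacency is the conservative
assumption); scenario completion times lognormal around the published
scenario means, scaled by a participant speed factor (0.95/1.05, SD 0.21,
within-scenario log-SD 0.196, so that standardized speed has SD ≈ 0.23);
and radio messages whose latent codings hit mention/error rates calibrated
to a mean total of ≈ 2.15/2.07 points.

Two calibrations were genuinely under-determined and are documented here
rather than hidden:

* **Knowledge–accuracy link.** The slope of the link is the calibration
  knob for the population Spearman correlation between knowledge and
  accuracy. At a slope of 0.02 — the value the regression table prints —
  the realized rank correlation overshoots (≈ 0.45) because the printed
  accuracy SDs cap the admissible noise; at 0.017 the correlation sits at
  ≈ 0.39 and the regression still recovers b ≈ 0.017, which rounds to the
  printed 0.02 with a bootstrap CI ≈ [0.01, 0.03]. The default is 0.017.
* **Word-count model.** Message length is core (informative phrases,
  which grow with the number of categories mentioned) plus lognormal
  filler with a between-participant trait (log-SD 0.44) and per-message
  noise (log-SD 0.30). This structure is needed to reproduce three
  published facts at once: the efficiency means (0.09/0.06), the
  efficiency effect size (d ≈ 1.13, which caps the between-participant
  efficiency SD at ≈ 0.03), and the cross-scenario reliability
  (standardized α ≈ 0.83, which demands that most of that SD be a stable
  trait). The published word-count means (32/46) cannot be reproduced
  simultaneously — a generative model honouring them makes efficiency too
  small and too noisy — so realized mean word counts sit near 25/40. The
  efficiency quantities take priority because they are the validated
  indicator; raw word counts were exploratory.

Gaze streams are generated as latent fixation sequences (per-category
duration normals truncated at 120 ms, dwell shares over the AOI categories
and background, 0.05° isotropic jitter) joined by 40 ms saccade sweeps, at
200 Hz over a 30 s window, with consecutive centres kept at least 2.5°
apart and sampled at least 1° inside their polygon. This makes the latent
event list a usable oracle: with zero jitter the detector recovers exactly
the latent fixation count (window boundaries may shift by a sample where a
window absorbs the start of a saccade sweep). Dwell shares are identical
in both groups, emulating the null result for visual attention. Subjective
ratings come from a participant trait plus per-scenario item noise split
so the composite has cross-participant SD ≈ 1.13 and five-scenario α near
0.86.

The generator's equal-attrition assumption: the published per-measure
sample sizes (74 for triage, 70 for transmission, 71/57 for gaze) are not
broken down by group, so missingness switches drop whole participants
completely at random, and the effect-size recomputations from printed t
statistics use group sizes 38/36 and 36/34. Missingness defaults to zero —
a complete study — and is opted into per indicator.

What passing tests on this generator do *not* show: robustness to real
eye-tracker noise (drift, blinks, variable sampling), to free-form German
radio speech (the rule-based coder is exact only on the controlled
lexicon), to scenario order effects or learning across scenarios (not
modeled), or to non-random dropout.

## Numerical choices and degenerate inputs

Dispersion uses the max of the axis ranges (not their sum), matching the
stated definition. Fixation duration is last-minus-first sample time.
Empty gaze streams yield empty fixation tables, not errors. Ties in AOI
assignment resolve to the smallest polygon; degenerate (self-intersecting
or zero-area) polygons are rejected at load time. The summary-statistic
and raw-data t-test entry points share one formula path and agree exactly.
Zero variance in both groups, singular MANOVA matrices and rank-deficient
regression designs raise classed degenerate-input errors naming the
problem. Bootstrap intervals are percentile intervals from 5000 seeded
case-resampling draws; BCa was considered and rejected as a default
because the percentile interval is the plainest reading of "bootstrapped
CI" and the two differ negligibly at n = 76 with this effect size.

The test and acceptance workloads use cohort replicates chosen to keep
Monte-Carlo error well below the assertion tolerances: 500 cohorts for the
calibration round-trips (standard error of a group mean across replicates
< 0.1 percentage points of accuracy), 1000 small null cohorts for the
family-wise error check, and 1000 messages for the coder round-trip.

## Known limitations

The panorama gaze model ignores head translation and depth, so AOI
geometry is static per scenario. The START classifier covers the standard
adult algorithm only (no jumpstart/paediatric branch, no intervention
effects such as bleeding control changing a patient's state). The
knowledge test is a reconstruction from the same assessment grammar as the
scenario patients, not the original instrument. Inter-rater agreement is
implemented as percent agreement (mention-level and error-level), matching
how the source reports it, not as a chance-corrected kappa.
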