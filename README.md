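# mcitriage

Performance-indicator scoring and known-groups validation for immersive
virtual-reality (iVR) mass casualty incident (MCI) triage training.

## The problem

When medical first responders (MFRs) train MCI triage in iVR, the software
can log everything: where trainees look during the first seconds on scene,
which triage colour they assign to each virtual patient and when, and what
they say to the control center over the radio. Turning those logs into
*validated* performance indicators requires (a) well-defined scoring rules
and (b) evidence that the scores separate groups that should differ —
experienced responders versus medically trained novices (known-groups
validity).

`mcitriage` implements the full chain for five indicator families:

* **Triage accuracy** — per scenario, the share of roster patients assigned
  their true START colour (untriaged patients count as incorrect; the last
  assignment to a patient wins), averaged over the five scenarios. The
  package ships a configurable START classifier (walking → green; not
  breathing after airway repositioning → black; respiration rate > 30/min,
  capillary refill > 2 s, absent radial pulse or failure to follow commands
  → red; otherwise yellow) and a 20-vignette triage knowledge test scored
  0–20.
* **Triage speed** — time to the last triage event, divided by the cohort
  mean of the same scenario, then averaged per participant; values < 1 are
  faster than average and each scenario column has mean exactly 1.
* **Visual attention** — I-DT (dispersion threshold) fixation detection on
  200 Hz gaze streams clipped to the 30 s orientation window, assignment of
  fixation centroids to area-of-interest (AOI) polygons (patients, safety,
  vehicle impact, distractor), and the two standard aggregates: duration of
  average fixation (DOAF) and fixation count (FC), first per scenario and
  then across scenarios.
* **Information-transmission efficiency** — SSSS content coding (scene,
  safety, situation, support; max 1 point each, 0.5 for an undetailed
  scene, −0.3 per error, floored at 0, ±2 patient-count tolerance in the
  two most complex scenarios), with the 0–4 total divided by the message
  word count, averaged over scenarios. A deterministic rule-based coder
  recovers codings from transcripts built on a controlled phrase lexicon.
* **Subjective performance** — mean of a 1–10 self-rating and a school
  grade mapped linearly onto 1–10 via `10 − 1.8·(grade − 1)`.

The validation battery mirrors standard practice: winsorization at
mean ± 3 SD, Levene-gated Student/Welch t tests (one-tailed for the
directional hypotheses) with Bonferroni–Holm correction over the three
indicator tests, Cohen's *d* (`d = |t|·sqrt(1/n₁ + 1/n₂)` from a t
statistic, or the pooled-SD form), MANOVAs with Pillai's trace for the two
gaze families, Spearman rank correlations, a centered OLS regression of
accuracy on triage knowledge with a 5000-draw case-resampling bootstrap,
and standardized Cronbach's α (`α = k·r̄ / (1 + (k−1)·r̄)`).

Because the underlying study's raw data are not public, the package
includes a synthetic cohort generator calibrated to the published
group-level moments (39 MFR / 37 non-MFR; knowledge 13.46 vs 10.89 points;
accuracy 84% vs 77%; standardized speed 0.95 vs 1.05; efficiency 0.09 vs
0.06; knowledge–accuracy Spearman ρ ≈ 0.40), so every stage of the
pipeline can be exercised and tested end to end.

## Worked example

```r
library(mcitriage)

cfg    <- generator_config(seed = 42)          # study-calibrated defaults
cohort <- generate_cohort(cfg, include = c("triage", "transmission", "subjective"))
scores <- score_cohort(cohort)                 # full scoring pipelines
report <- run_battery(scores$indicators, scores$per_scenario,
                      battery_config(n_boot = 1000))
report
```

```
<mci_battery> known-groups validation report

Holm-corrected hypothesis tests (MFR vs non-MFR):
  indicator variant statistic   df  p_value   p_holm cohen_d
   accuracy   welch      2.78 58.6 3.60e-03 7.21e-03   0.639
  std_speed student     -1.26 74.0 1.05e-01 1.05e-01   0.290
 efficiency   welch      4.65 62.3 8.75e-06 2.62e-05   1.068

Knowledge-score known-groups test:
 statistic   df  p_value cohen_d
       4.3 71.5 5.31e-05   0.987

Standardized Cronbach alpha:
           indicator alpha
            accuracy 0.840
              time_s 0.853
 efficiency_scenario 0.793
 subjective_scenario 0.866
```

The three hypothesis rows are the directional MFR-vs-non-MFR tests after
Holm correction: in this simulated cohort accuracy and efficiency separate
the groups (d = 0.64 and 1.07), speed does not reach significance at
n = 76 (d = 0.29 — its true calibrated effect is ≈ 0.42, which a single
cohort detects only with moderate power). The α block is the
internal consistency of each indicator across the five scenarios.

The regression block reproduces the knowledge → accuracy link with
bootstrap percentile intervals:

```r
report$regression
#>         term estimate std_error  p_value ci_lower ci_upper
#>  (Intercept) 0.786751   0.01776 5.59e-54  0.74837  0.82524
#>  knowledge_c 0.017060   0.00476 6.07e-04  0.00791  0.02730
#>        age_c 0.000127   0.00280 9.64e-01 -0.00441  0.00484
#>       gender 0.025371   0.01789 1.60e-01 -0.00803  0.06172
```

`tidy(report)` and `glance(report)` return the test table and a one-row
summary; `plot_indicator_densities(scores$indicators)` and
`autoplot(report)` draw the group densities and the effect-size overview.
`simulate_study()`, `score_study()` and `analyze_study()` run the same
pipeline through a self-contained study directory on disk
(CSV/JSON-lines files plus a seed-stamped manifest).

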