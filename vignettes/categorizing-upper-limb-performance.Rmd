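---
title: "Categorizing upper-limb activity performance from bilateral wrist accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Categorizing upper-limb activity performance from bilateral wrist accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ulperf)
```

## The measurement problem

In-clinic assessments measure what a person *can* do with their upper
limbs; wrist-worn accelerometers measure what they actually *do* over a
day of ordinary life. `ulperf` implements a complete analysis chain for
the second kind of measurement: bilateral raw accelerometry is reduced to
twelve per-subject activity performance variables, subjects are
categorized by PCA plus k-means with formal model-fit adjudication, and
the resulting categories and components are validated against self-report
instruments. Because real wrist-sensor cohorts are rarely distributable,
the package also includes a synthetic cohort generator that reproduces the
statistical structure the analysis relies on, so every stage is
exercisable and testable in code.

This vignette explains the models and conventions behind each stage, the
parameters a user might want to change, and what the synthetic cohorts do
and do not establish about real data.

## Signal processing

Two processing paths run per limb:

* **Counts path.** The triaxial 30 Hz signal is bandpass filtered at
  0.25–2.5 Hz (order-4 Butterworth applied forward–backward, so zero
  phase), converted to activity counts, and summarized in 1 s epochs as
  the vector magnitude of the per-axis counts. The count conversion
  follows the structure of the open-source replication of the wrist
  activity-count algorithm: clip to ±2.13 g, quantize at 1/32 g, rectify,
  zero values under a 2-unit deadband, decimate to 10 Hz, and sum per
  epoch, flooring to integers. We chose zero-phase filtering (rather than
  the causal cascade used by device firmware) so that no limb acquires a
  phase lag relative to the other — jerk and smoothness comparisons
  between limbs would otherwise inherit a systematic artifact. The
  constants are package conventions, documented here precisely because
  bit-exact parity with proprietary device software is not attainable;
  the package also reads precomputed 1 Hz counts CSVs for data exported
  directly from vendor software.
* **Raw path.** Variables that need full bandwidth (jerk asymmetry,
  spectral arc length) are computed from the vector magnitude of the
  0.2–12 Hz zero-phase filtered signal. Both filters subtract the signal
  mean before filtering; the passband excludes DC, and demeaning removes
  the slow edge transients that forward–backward filtering would
  otherwise leak into short recordings.

A subject enters analysis only with a **bilateral valid day**: at least
24 h (86,400 valid 1 s epochs, boundary inclusive) on *each* wrist, after
excluding epochs inside wear-log off-intervals. Accumulation need not be
contiguous — the inclusion rule counts wear, not clock span.

## The twelve performance variables

An epoch counts as *movement* when its activity count exceeds 2 — applied
here to the vector-magnitude counts, which the docs flag as a convention
since a per-axis reading is also defensible. The duration variables are
hours of moving epochs (per limb, and "only" times when exactly one limb
moves); intensity is the median moving-epoch count of the non-preferred
limb and the bilateral sum of the two limbs' medians; variability is the
sample SD of the non-preferred limb's moving-epoch counts. Symmetry is
carried by the use ratio (non-preferred ÷ preferred hours) and the
magnitude ratio, which defaults to the natural-log scale (so 0 means
equal intensity and the value is antisymmetric under limb swap); the raw
ratio is available by argument.

Two variables need conventions the literature leaves open:

* **Jerk asymmetry.** Per-limb jerk is summarized as the mean absolute
  central-difference derivative of the filtered vector magnitude per unit
  time (median available by argument); the index is the normalized
  difference (J_np − J_p)/(J_np + J_p), which is bounded in [−1, 1] — the
  bound is what forces the normalized-difference reading of the index's
  definition. Note that over day-long recordings the mean jerk reflects
  *how much* a limb moves as well as how roughly, so an impaired
  non-preferred limb that moves rarely typically yields a negative index.
* **SPARC.** The spectral arc length is the negative arc length of the
  peak-normalized Fourier magnitude spectrum up to an adaptive cutoff:
  default maximum frequency 10 Hz, amplitude threshold 0.05, FFT
  zero-padded by 2^4 — the defaults of the metric's source publications.
  It is computed on the vector magnitude of the whole filtered series
  (not per movement bout), matching its use on day-long recordings;
  per-axis computation was the alternative we did not take.

Subjects missing any variable of the active set (e.g. no moving epochs on
the non-preferred limb) are dropped from PCA/clustering for that set,
with a warning carrying the count.

## Categorization and model-fit adjudication

Variables are z-scored per column before any multivariate step, since
hours, counts and ratios live on different scales; the (mean, SD) scaler
is retained so new subjects can be projected later. PCA runs on the
z-matrix. Because a principal component's sign is arbitrary, every
component is anchored to load non-negatively on preferred time; the flip
multiplies loadings and scores together, so explained variances and the
internal loading structure are untouched, and loadings become comparable
across the nested variable sets {v12, v9, v7, v5}.

Clustering is k-means (Lloyd's algorithm, best of `n_init` random
restarts, 300 iteration cap) **on the z-scored variables**, not on PC
scores; PC space is used for visualization. This mirrors the standard
workflow in this literature and is exposed as a deliberate design choice.
Cluster labels are canonically reordered by ascending PC1 centroid so
that label 1 is always the least-active profile and reports are stable
across runs. The diagnostics — WSS elbow, mean silhouette width, and the
gap statistic (PCA-aligned uniform-box reference, squared distances,
B = 100 reference sets, suggested k by the one-standard-error rule) —
support a k = 1..10 scan.

Formal adjudication runs over the 16-cell grid of variable set × k ∈
{2, 3, 4, 5}: each cell records the MANOVA-style variance explained,
100·(1 − WSS/TSS), and an AIC under a spherical Gaussian within-cluster
model,

AIC = n·p·(log(2π·WSS/(n·p)) + 1) + 2·k·p,

with centroids as parameters. The additive constant matters and is part
of the package convention: it grows with the number of variables p, which
is what lets a parsimonious five-variable model beat a twelve-variable
one at comparable fit. Absolute AIC values are not comparable across
datasets; only within-grid orderings are interpreted. Ties break toward
smaller k, then fewer variables. One property of this convention worth
knowing: on continuous or Gaussian-mixture-like data the per-k penalty
2·p is small relative to the likelihood gain of an extra centroid, so AIC
decreases in k and the grid minimum sits at the upper k boundary — the
adjudication is therefore meaningful only over a bounded, pre-declared
candidate grid (here 2–5, the range the scan diagnostics support), not as
an open-ended search.

## Validity

Each self-report outcome is regressed (OLS) on categorical cluster
indicators, on the two PC scores, and on each single variable;
`build_validity_table()` reports unadjusted R² (adjusted R² alongside),
complete cases per cell, and an F-test flag at α = 0.05 without
multiplicity correction — cells are flagged individually, so readers
should treat the flags as descriptive. Administration rules are enforced
by construction: the MAL-AoU exists only for neurological subjects
(stroke, MS) and the DASH only for musculoskeletal ones (fracture,
shoulder pain, breast cancer), so those columns analyze only the
applicable subgroups. The depressive-symptom score (CES-D) is the
divergent control: it is generated independently of the latent
performance trait, and its column of R² values is expected to stay under
0.1.

A structural point the package demonstrates (and tests): when an outcome
is generated as a linear function of PC1 plus noise, the R² from the two
continuous PCs exceeds the R² from the five cluster indicators in almost
every replicate — discretizing a continuum into categories discards
within-category variation that the outcome still tracks. This is the
mechanism behind preferring continuous representations of UL performance.

## The synthetic cohort generator

Each subject carries a latent profile: `latent_performance` ∈ [0, 1]
(1 = unimpaired), `asymmetry` ∈ [0, 1] (0 = symmetric limb use),
`activity_level` > 0, and a concordance flag (whether the dominant limb
is the affected one — drawn per-group at the reported demographic
proportions, and deliberately *not* used in signal generation, since the
analysis is concordance-agnostic once limbs are relabeled
preferred/non-preferred). Group hyperparameters place controls high on
performance with near-zero asymmetry (capped at 0.15), stroke lowest and
most variable, with MS, distal fracture, proximal pain and breast cancer
in between; the default group sizes are 138/49/19/40/55/23 (324
subjects). These anchors are the package's own choices: the published
record for this design shows only qualitative group orderings in density
plots, so the generator aims to reproduce orderings and overlaps, not
numeric densities.

Movement is a rest/movement bout alternation: lognormal bout lengths
(median ≈ 5 s movement), with the long-run moving fraction of the
preferred limb set by activity level (≈ 0.12 + 0.25·activity, so roughly
7–9 h of movement per 24 h at default activity). The non-preferred limb's
bout frequency and amplitude shrink by the factor
(1 − asymmetry)·(0.4 + 0.6·latent), which is 1 for a symmetric unimpaired
profile and 0 in the fully asymmetric limit — this single factor is what
encodes impairment into use ratio, times, magnitudes and variances at
once, and it is monotone in the latent trait by construction. Raw signal
bouts are Hann-windowed bursts with 0.5–3 Hz carriers plus a 6–10 Hz
component whose relative amplitude grows as performance falls (the
"jerky" component), on top of gravity and sensor noise; this gives
independent control of duration, intensity, variability and symmetry.

Two scales of realization exist, and this is a deliberate design
decision: full-duration raw generation (`simulate_limb_signal()`) feeds
the raw→counts path and its tests, while cohort-level generation produces
the full-day 1 Hz count series directly from the same bout model plus a
raw excerpt (default 10 min per limb) for the jerk/SPARC variables. A
full-day 30 Hz bilateral raw cohort at n = 324 would be ~5×10⁹ samples
and serves no statistical purpose the two-scale version does not.

Self-reports are monotone transforms of the latent trait plus Gaussian
noise — PROMIS anchored at 50 for an unimpaired subject with slope 35 and
noise SD 8; MAL-AoU = 5·latent on its 0–5 scale; DASH = 90·(1 − latent)
on 0–100 (lower is less disability); ACS and EuroQoL similarly — while
CES-D is lognormal around 9 points, independent of the trait. The noise
scales were calibrated once, from the slope-to-noise ratios, so that
single-variable R² against the PROMIS-like outcome lands in the 0.1–0.4
band typical of this literature; they are constructor defaults, not
fitted quantities.

**What passing tests on synthetic cohorts show — and what they do not.**
They show the pipeline is internally correct: formulas match hand
computations, invariants (bounds, antisymmetries, monotonicities) hold,
and the adjudication recovers the structure the generator put in. They do
not show that real cohorts contain five clusters: the generator has no
circadian structure, no non-wear misclassification, no device noise
floor, no heavy-tailed activity distributions, and its group archetypes
are stylized. Conclusions about real populations require real recordings.

## Numerical and scale choices

* Epoch boundaries align to recording start, not wall clock.
* Times are kept in hours at full floating precision; counts are
  non-negative integers (floored before the epoch vector magnitude).
* k-means uses `n_init = 25` restarts by default in the adjudication grid
  and scan (the solutions on these data are stable well below that;
  `assess_cluster_recovery()` uses 100 restarts, matching its
  sample-size-analysis setting), fixed seed 20250725, with all stage
  seeds derived from one root seed so a single flag reproduces a run.
* The sample-size simulation draws five cluster centroids as a randomly
  rotated regular simplex whose coordinates differ by a per-variable
  separation of 1–2 within-cluster SDs (Euclidean distance √5 times
  that). We read "centroid separation in SD" per standardized variable:
  under the literal total-Euclidean reading, five clusters at distance
  1–2 SD in five dimensions are largely overlapping and no method
  recovers labels at the accuracy this design analysis requires, so that
  reading is inconsistent with the analysis it supports.
* Degenerate inputs propagate as typed missing values (no moving epochs,
  zero jerk on both limbs, all-zero SPARC input) or errors naming the
  offending quantity (zero-variance column, invalid wear log, valid-day
  failure).

## Problem sizes

The shipped tests and the acceptance script run at the sizes the analyses
are defined at: the default six-group cohort (n = 324, 24 h bilateral
counts, 10 min raw excerpts), 100-replicate Monte-Carlo runs at n = 200
for label recovery, and 1,000 randomized series pairs for the jerk bound.
Unit tests use micro-fixtures (6–300 epochs) where exact hand computation
is possible.

## Known limitations

* Counts are an open re-implementation, not device-software output;
  absolute count magnitudes differ from vendor exports, though all
  downstream variables are rank- and threshold-stable under the
  documented constants.
* Mean-jerk aggregation entangles movement quantity with movement
  roughness on day-long recordings (see above); bout-level smoothness
  analysis is out of scope.
* The AIC convention supports within-grid comparisons only; its absolute
  values have no cross-dataset meaning, and on continuous data the chosen
  k sits at the grid boundary by construction of the penalty.
* No imputation: wear-log gaps simply remove epochs, and subjects failing
  the bilateral valid-day rule are excluded rather than rescued.
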