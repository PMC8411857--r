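---
title: "Archetypal decomposition of 24-2 visual fields: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Archetypal decomposition of 24-2 visual fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfarch)
```

## The model

A Humphrey 24-2 visual field is summarised here by its 54 total-deviation
(TD) values: per-location differences, in dB, between measured sensitivity
and the age-matched norm.  Archetypal analysis represents each field
$x_i \in \mathbb{R}^{54}$ as a convex combination of $k$ archetypes,

$$x_i \approx \alpha_i Z, \qquad \alpha_{ij} \ge 0,\ \textstyle\sum_j \alpha_{ij} = 1,$$

where the archetypes $Z$ are themselves constrained to be convex
combinations of the observed fields, $Z = \beta X$ with $\beta$ rows on the
probability simplex.  Archetypes therefore sit on or near the boundary of
the data's convex hull: they are *extremal* field patterns, and the weights
$\alpha_i \cdot 100$ quantify, in percent, how much of each pattern a given
field contains.  Weights always sum to 100%.

In eyes with papilledema from idiopathic intracranial hypertension the
extremal patterns are clinically recognisable — blind-spot enlargement,
arcuate and partial arcuate nerve-fiber-bundle loss, nasal defects,
hemianopic and quadrant defects, general depression, and the normal field —
which is what makes the decomposition useful: the weights turn a
qualitative reading into a quantitative, reproducible measurement.

## Fitting

`fit_archetypes()` alternates three steps until the residual sum of squares
(RSS) stabilises: (1) solve each field's weights $\alpha_i$ given $Z$;
(2) update the unconstrained archetype positions $\tilde Z$ from the normal
equations; (3) project $\tilde Z$ back onto the data's convex hull by
solving the $\beta$ rows.  Both constrained subproblems are simplex-
constrained least squares, solved by Lawson–Hanson non-negative least
squares on a design augmented with a penalty row of weight $M$ that forces
the coefficients to sum to one (the classical device for this model).  The
residual sum-to-one violation is of order $1/M^2$; coefficient rows are then
renormalised so the constraint holds to machine precision.

Choices that matter:

* **Penalty weight `M`** — default `200 * max(abs(x), 1)`, i.e. 200 times
  the data scale.  Large enough that the constraint violation is far below
  the 1e-6 tolerance the decomposition contract promises, small enough not
  to degrade the conditioning of the Gram matrices (which the solver uses
  for speed).
* **Initialisation** — furthest-sum seeding: archetypes start at mutually
  distant data rows, which places them near the hull boundary from the
  first iteration.  The original report is silent on initialisation, so
  `n_restarts = 5` independent seeded restarts are run and the best final
  RSS kept; with the same `seed` the fit is bit-reproducible.
* **Convergence** — relative RSS change below `tol = 1e-6`, capped at
  `max_iter = 200` iterations; non-convergence returns the best iterate
  with a warning.  The per-iteration RSS history is stored and is
  non-increasing up to the tolerance (the hull-projection step is not an
  exact coordinate descent, so tiny transient increases are possible; the
  best iterate is always the one returned).
* **Ordering** — archetypes are sorted by relative weight (the mean of
  their weights over the fitted fields), descending, the convention used
  when such models are displayed; ties break by average TD, then index.
* **Degenerate cases** — `k = 1` returns the column mean (the only convex
  combination possible when weights are forced to 1); `k = n` is allowed
  with a warning (the archetypes are then the data rows themselves).

## Choosing the number of archetypes

`rss_curve()` computes, for each candidate $k$ (default 2–20), the
training RSS of a full-data fit and a 10-fold cross-validated RSS: rows are
shuffled once per seed, each fold is held out in turn, and held-out fields
are decomposed against the model fit on the remaining folds.  The original
description plots one RSS curve and selects "where the curve flattens";
it is ambiguous whether that curve was the training or the CV one, so both
are always computed and exported, and the **CV curve drives the default
selection** (it is the one that penalises overfitting).  `select_k_elbow()`
makes the flattening rule explicit: after min–max normalising both axes,
it returns the $k$ with maximal perpendicular distance to the chord joining
the curve's endpoints (a scale-free corner detector); a relative-drop rule
(first $k$ improving by less than 5%) is available as an alternative.  A
perfectly straight or flat curve returns the smallest $k$ with a warning.

## Calibrating the meaningful-weight threshold

Even healthy eyes decompose into nonzero weights on abnormal archetypes,
because of test–retest noise.  The threshold separating signal from this
fluctuation is calibrated on a normal control cohort
(`calibrate_controls()`): every control field is decomposed into the
disease model; per-archetype weights are averaged within eye and the mean
and 95% CI (normal approximation, $\pm 1.96\,\mathrm{SE}$) taken **across
eyes**, so repeated tests of one eye do not shrink the interval; the weight
*change* per eye is the mean absolute deviation of follow-up weights from
that eye's first visit (baseline-anchored absolute change — the reference
description does not fix signed vs absolute or pairwise vs anchored, and
the anchored absolute version is the conservative reading; a seeded
bootstrap CI is available as an option).  "Normal" archetypes — identified
by average TD at or above −1 dB, or an explicit list — are excluded, and
the threshold is

$$\mathrm{threshold} = \lceil \max(\text{abnormal upper 95\% limits}) \rceil + \mathrm{margin}.$$

The default margin of 2 percentage points reproduces the published
calibration step (largest abnormal upper limit 7% → threshold 9%) and
absorbs the multiplicity of scanning 14 archetypes at once; it is a
configuration default, not a claim about the original authors' exact rule.

Two edge decisions were genuinely open.  First, a model fit to a purely
abnormal cohort may have *no* archetype clearing the −1 dB normality
cutoff; the calibration then falls back to treating the single
highest-average-TD archetype as the normal reference (with a warning)
rather than letting the threshold degenerate towards 100%.  Second, the
calibration's consistency is monitored as the false-positive rate of
meaningful-abnormal calls in fresh synthetic controls, counted per
(eye-visit, abnormal archetype) opportunity — the reading coherent with
the per-archetype 95% confidence level the threshold is built from; the
fraction of *visits* with at least one call necessarily compounds across
the abnormal archetypes and is not the calibrated quantity.

## Scoring

* `meaningful_archetypes()` — archetypes at or above the threshold
  (boundary inclusive: 9% counts when the threshold is 9).
* `dominant_archetype()` — the unique archetype carrying ≥ 50% of a field;
  an exact 50/50 tie yields none.
* `assign_signs()` / `at_sum()` — the signed composite: archetypes ranked
  by average TD, the better half positive, the worse half negative (odd
  $k$ puts the median archetype positive; an explicit split can be
  supplied).  The score $\sum_j s_j w_j \in [-100, 100]$ falls as abnormal
  weight accumulates and, unlike MD, is not dominated by the central
  points.
* `match_classification()` — set-based comparison of feature tags between
  the dominant archetype and an expert label: equal sets are an exact
  match, a nonempty intersection partial, disjoint sets different.  The
  archetype→tag map is a user-supplied clinical judgment, not computed.
* `cohort_report()` — frequency and count tables, Spearman correlations
  (average ranks; two-sided p by the t approximation), Wilcoxon rank-sum
  group comparisons and a chi-square test on the above-threshold table.
  Raw p-values are reported by default, matching routine practice; a Holm
  adjustment flag exists.

## Cohort curation rules

`read_cohort()` ingests one row per field (CSV schema documented there)
and applies the trial's reliability cutoffs: fixation losses < 33% and
false positives < 15%, else the field is unreliable and
`filter_reliable()` drops it.  Replicate fields at one visit are averaged
pointwise (`average_replicates()`).  `detect_treatment_failure()`
implements the two-stratum confirmed MD-drop rule *as printed* in its
source: a drop of ≥ 2 dB from baseline when baseline MD ≤ −3.5 dB,
otherwise ≥ 3 dB, confirmed by the next available field.  (The printed
strata overlap — read literally, "≤ −3.5" and "between −3.5 and −7"
cover the same eyes — and this package resolves the overlap in favour of
the first clause, which is also what the rule's own worked example
requires.)  `curate_outcome_window()` truncates follow-up at month six,
substitutes the failure-visit field forward for treatment failures, keeps
only reliable fields for performance failures, and averages replicates.

Two conventions deserve note:

* **Laterality.**  Left-eye fields are mirrored into right-eye orientation
  at load so that one model serves both eyes.  The 24-2 lattice is not
  exactly left–right symmetric: the two nasal-extension points at
  (−27°, ±3°) have no temporal counterpart, so they map to themselves;
  the remaining 52 locations mirror exactly and the permutation is an
  involution.  Whether the original analysis mirrored at all is not
  stated; mirroring is the default and can be disabled.
* **Global indices.**  The instrument's MD/PSD are variance-weighted by
  proprietary coefficients.  For synthetic and replicate-averaged fields
  this package uses surrogates — the unweighted mean and SD of the 52
  non-blind-spot TD values — documented as approximations.
* **Fitting set.**  The model is fit on all reliable, *unaveraged* fields
  (matching the reported field counts); the curated per-visit averages
  feed the downstream scoring.  Both pathways are exposed.

## The synthetic world

`generate_cohort()` and `generate_controls()` stand in for the trial data,
which have no public accession.  Their defaults are the stated conditions
of that world, fixed once: baseline study-eye MD in −7 to −2 dB (the
trial's inclusion window), two baseline replicates and monthly visits
through month six, Dirichlet mixing concentration 0.3 over the eight
prototype maps (small concentration puts most fields near single
patterns, as clinical fields are), measurement noise iid Gaussian with SD
1.5 dB per location truncated to [−40, 10] dB, a treatment-failure
fraction of 7/165 and an unreliable-field fraction of 2.5% (both the
trial's observed rates), and 61 control eyes with ~9 visits each
(≈ 568/61).  Recovery experiments use 1 dB noise and 500 fields where the
protocol under test specifies them.

The generator emulates the *structure* of the data — mixtures of
recognisable extremal patterns, replicate tests, improvement and
worsening trajectories, reliability metadata — but not everything real
fields do: noise is spatially independent (real TD noise is correlated
and eccentricity-dependent), prototypes are hand-authored shapes rather
than estimated archetypes, and no demographics, acuity or papilledema
grades are simulated beyond placeholders.  A green recovery test
therefore establishes that the algorithms do what they claim on data of
known structure; it does not certify the clinical archetypes themselves,
which require the original cohort.

## Numerical notes and limitations

* Decomposition weights are reported at full precision; rounding to
  integer percentages is a display concern only.
* Models serialize to JSON with 17 significant digits, so save/load
  round-trips are bit-exact.
* The per-field decomposition objective has been checked against
  brute-force simplex grid search, and small-instance fits against
  exhaustive search over hull-boundary archetype placements; both live in
  the test suite as oracles independent of the fitting code.
* The model-order experiments in the test suite run the planted-prototype
  generator at 200 fields per seed (not the 500 used for the
  parameter-recovery check) to keep the cross-validation sweep inside its
  runtime budget.
* No robust, weighted, sparse or kernel variants of the decomposition are
  provided, and no longitudinal outcome prediction: the composite score
  and weight trajectories are descriptive.
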