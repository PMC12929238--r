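---
title: "Resampling-based onset latency analysis for visual-world eye-tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resampling-based onset latency analysis for visual-world eye-tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In visual-world-paradigm (VWP) experiments, participants' gaze to pictures is
recorded while they process spoken language. Beyond *whether* two groups (or
conditions) differ in their looking behaviour, researchers increasingly ask
*when* an effect begins: does one group's preference for the target picture
emerge later than the other's? `vwplat` implements a family of
resampling-based procedures for estimating that effect-onset latency per
group, forming the between-group latency difference, and attaching inferential
uncertainty to it — together with a Monte Carlo engine for studying the power,
Type I error, and coverage of every variant of the procedure, and a synthetic
gaze-data generator so the whole pipeline can be exercised and tested without
any external dataset.

The analysis skeleton is a three-step procedure:

1. **Estimate a latency per group.** The analysis window (region of interest,
   ROI) is divided into fixed-width bins; a statistical test for the effect of
   interest is run in every bin; the latency is the start time of the first
   bin (or first run of bins) where the effect is reliably present. The
   latency difference is `shifted − baseline`.
2. **Bootstrap.** The data are resampled `B` times (2000 by default); the
   latency difference is recomputed on every resample, giving a bootstrap
   distribution from which confidence intervals are built.
3. **Permutation test.** Group labels are reassigned at the participant level
   `P` times (1000 by default) to build the null distribution of the latency
   difference; the two-sided p-value is the plain proportion of null values at
   least as extreme as the observed difference.

## Binning and binarization

`binning_config()` fixes the ROI geometry. The default follows the
sentence-processing setup the package's defaults are organized around: a
2000-ms window starting at the disambiguating word, shifted by a 200-ms
saccade-execution offset on both boundaries, and cut into forty 50-ms bins
(a 40-ms variant suits data downsampled to 50 Hz, where two samples fall in
each bin). Bins are half-open `[start, start + width)`, so a sample exactly at
the ROI end is excluded and the bin count is exactly
`(roi_end − roi_start) / width`.

Within each participant × trial × bin cell, looks to excluded areas of
interest (whitespace, by default) are dropped and the proportion of remaining
samples on the target is computed. With high-rate autocorrelated gaze data
these proportions are almost always 0 or 1, and the pipeline **binarizes**
them: proportions ≥ 0.5 become 1, the rest 0. The boundary convention (0.5
rounds *up*) matters in sparse webcam-like data and is tested explicitly.
Cells in which a trial retains no samples emit no record rather than an
imputed value; the pooled per-bin tests simply use the data that exist.

## Per-bin tests

Two per-bin tests are provided, matching the two data shapes the package
accepts:

* **Pooled logistic test** (trial-level binary data). All trials of all
  participants of one group in one bin are pooled; an intercept-only logistic
  model then has the closed form `b = log(p̂ / (1 − p̂))` with Wald standard
  error `1 / sqrt(n p̂ (1 − p̂))`, and a two-sided Wald test against chance.
  Under complete separation (all or no trials on target) the Wald statistic
  collapses, so the implementation falls back to the exact binomial test
  against 0.5 (`p = 2 · 0.5^n`), reporting the estimate as ±∞ and passing the
  effect-size threshold only in the all-target direction. A mixed model with
  participant intercepts is a defensible alternative here; the pooled fit was
  chosen because it is the model the procedure literally describes, it is
  deterministic and closed-form, and it must run millions of times inside the
  resampling loops. The pooled fit is cross-checked against an iteratively
  reweighted ML fit in the test suite.
* **Relative-proportion t-test** (participant-level proportion data, as in
  shared word-recognition datasets without trial-level records). Per
  participant and bin, the relative competitor proportion
  `competitor / (competitor + unrelated)` is tested against 0.5 with a
  one-sample t-test. Participants with an undefined ratio (both proportions 0)
  are excluded bin-wise; zero-variance bins are degenerate and never
  significant.

"Significant" always means *two-sided p below α and the estimate in the
positive direction*; this encodes "significantly above chance" without
committing to a one-sided α.

## Latency measures

Four measures are implemented (`latency_config()`):

* `consecutive`: first of `k = 5` consecutive significant bins;
* `consecutive_threshold`: as above, with every bin of the run additionally
  above an effect-size threshold;
* `holm`: first bin significant after Holm–Bonferroni correction over the `m`
  bins, in the positive direction;
* `holm_threshold`: the Holm measure with the threshold requirement on that
  bin.

The effect-size threshold is 0.2 on the log-odds scale (≈ 55% target
probability) for the logistic test and 0.03 on the raw
competitor-minus-unrelated proportion scale (≈ 57% relative proportion) for
the t-test. Two readings of the consecutive + threshold measure are possible —
threshold required in all `k` bins of the run, or only in the first — and the
package requires it in **all** `k` bins, reading the run as a joint per-bin
criterion; this choice can only delay an onset, never advance it, and the
monotonicity is property-tested. Latency is reported as the **start** time of
the qualifying bin.

When no bin qualifies, the estimate is **censored at the ROI end** rather than
dropped. This keeps every bootstrap and permutation distribution at its full
length `B` (or `P`) and is this package's convention (how undetected onsets
were handled in the original resampling loops is not documented); the censored
fraction is always carried alongside the estimates, and aggregation reports it
rather than silently absorbing it. Censoring compresses differences toward the
ROI edge, which is visible as mild attenuation in parameter-recovery checks.

## Resampling schemes

* **By-participant bootstrap** (`bootstrap_by_participant()`): draws `n`
  participants per group with replacement; a drawn participant contributes all
  of their trials, so within-trial and within-participant dependencies are
  preserved. Participants drawn more than once enter the pooled counts with
  their multiplicity — the count-matrix implementation makes the "clone
  relabeling" automatic. With condition-stratified designs, draws preserve
  per-condition counts.
* **Stratified bootstrap** (`bootstrap_stratified()`): keeps every participant
  and resamples the `m` trial-level binary values within each
  group × participant × bin stratum with replacement, independently across
  strata — the scheme that breaks within-trial autocorrelation and does not
  propagate between-participant variability into the resamples. Since every
  downstream statistic depends on the data only through stratum success
  counts, the stratum draw is implemented as the distributionally exact
  `Binomial(m, s/m)` draw on the count; this is an implementation detail, not
  an approximation, for binarized data.
* **Participant-level permutation** (`permutation_test()`): whole participants
  are reassigned to groups of size `n`; the two-sided p-value is
  `#{|null| ≥ |observed|} / P`, with no smoothing — p-values live on the
  lattice `{0, 1/P, …, 1}`.

## Confidence intervals

`bootstrap_ci()` implements five constructions: percentile, normal
(bias-corrected, `observed − bias ± z·sd`), empirical (basic / backwards
percentile), bias-corrected (BC), and accelerated bias-corrected (BCa). The
"accelerated bias-corrected (ABC)" label in this literature is ambiguous
between jackknife-based BCa and the analytic approximate-bootstrap-confidence
method; this package implements **jackknife BCa** — the standard practice —
with leave-one-*participant*-out jackknife values, because the participant is
the resampling unit. Numerical conventions, fixed for reproducibility:

* empirical quantiles use linear interpolation of order statistics
  (`type = 7`, R's default);
* the BC bias constant uses the strictly-less count,
  `z0 = Φ⁻¹(#{boot < observed} / B)`, ties with the observed value excluded;
  a one-sided degenerate count clamps `z0` to `±Φ⁻¹(1/(B+1))` and flags the
  interval's diagnostics;
* a constant bootstrap distribution yields the zero-width interval at that
  value for every method;
* Holm uses the monotone adjusted p-values of `stats::p.adjust` (rejection
  iff adjusted p ≤ α, equivalent to the step-down rule), with stable
  tie-breaking in bin order.

All five constructions are verified against `boot::boot.ci` on continuous
data, and against symmetry identities (symmetric distribution ⇒ BC =
percentile; symmetric jackknife ⇒ BCa = BC) and the degenerate cases in the
test suite.

## The Monte Carlo engine

`build_plan()` enumerates a grid of cells (group size × effect size ×
per-participant noise SD) and reports the planned accounting — simulations,
resampled datasets `n_sims · (B + P [+ B])`, and per-bin model fits
`resamples · m · 2` — which reproduces the published study-scale arithmetic
exactly (30,000 / 48,000 / 18,000 / 20,000 / 40,000 simulations; 156,000 in
total). `run_simulation()` executes one iteration: sample `2n` participants
(without replacement from a pool, with replacement when the pool is too
small, condition-balanced when requested), split into Baseline and Shifted,
add the cell's shift to every Shifted-group time stamp, optionally add one
`Normal(0, sd)` offset per participant, bin, estimate all four measures, and
run the resampling tests. Per-simulation child seeds are derived
deterministically from the master seed, cell, and simulation index, so cells
can run in any order with identical output.

Aggregation (`aggregate_cell()`) follows the strict counting rules: bootstrap
power counts CI lower bounds **strictly above 0**; Type I error counts
intervals **strictly excluding 0**; permutation power requires a positive
observed difference *and* p < α; coverage counts intervals containing the
true shift. All rates come with Wilson score intervals.
`pooled_shift_estimates()` exploits the fact that injecting a shift merely
translates the bootstrap distribution: null-cell CI bounds are translated by
each effect size and re-scored, pooling simulations into more precise
estimates.

## The synthetic generator

The original studies resample real datasets; no generative model is published
for VWP gaze data. The generator (`synthetic_spec()`, `generate_gaze()`) is
therefore this package's own model, built to reproduce the *qualitative*
features the procedures are sensitive to:

* a per-participant onset `τᵢ = τ_base + Δ_group + Normal(0, σ_subj)`, with
  trial-level jitter `Normal(0, σ_trial)`;
* a marginal target probability at chance (`p_pre = 0.5`) before the onset,
  ramping linearly to a plateau `p_max` over `ramp_ms` (a transient variant
  decays back, for cohort-competitor-like effects);
* strong within-trial autocorrelation via a persistence parameter `ρ`: each
  sample repeats the previous AOI state with probability `ρ`, otherwise
  redraws from the marginal. This matters because the stratified bootstrap's
  behaviour hinges on breaking exactly this dependence;
* whitespace looks substituted with probability `p_whitespace`;
* fixed-rate sampling (infrared regime) or lognormal inter-sample gaps at a
  mean rate (webcam regime, right-skewed and variable as observed in web
  data, typically in the 1–50 Hz range).

Defaults — 24 participants per group, 24 trials, onset 800 ms, `σ_subj` 60 ms,
`σ_trial` 30 ms, `p_max` 0.95, ramp 200 ms, `ρ` 0.9, 5% whitespace, 120 Hz,
2400-ms trials — describe a realistic infrared sentence-processing experiment
with an early, lasting target preference: sample sizes and rates mirror the
seed-data regime the procedures were originally evaluated in, and onset/ramp
values are typical of verb-driven disambiguation. They are conventions of this
package, chosen once; the generator's ground-truth sidecar makes every run
checkable against the true onsets.

With `ρ > 0` and a time-varying marginal, the realized target probability lags
the nominal ramp slightly (states persist from the recent past); calibration
tests therefore test the pre-onset window and the plateau, not the ramp
midpoint. What the generator does **not** emulate: saccade kinematics and
fixation durations, item-level variability, smooth participant-specific
plateau differences, drift or loss of tracking over a session, and anything
about calibration quality. Passing tests on synthetic data therefore establish
the procedures' statistical behaviour under a clean, known-truth model — not
that any particular real dataset satisfies that model.

## Problem sizes used in the checks

The shipped tests run the Monte Carlo properties at desk scale, chosen so the
whole suite completes in minutes while keeping Monte Carlo error well below
the effects being asserted: 300 null simulations with 200 permutations for the
Type I error check (2-standard-error slack), 100 simulations with `B = 200`
for the ±1-bin parameter-recovery check at a 300-ms true shift, and 200
simulations with `B = 200` per scheme for the stratified-vs-by-participant
false-positive ordering under 200-ms timing noise. The full published grids
are enumerated (and their accounting verified) but not executed.

## Known limitations

* Between-group comparisons only; within-subject designs need a different
  permutation scheme and are out of scope.
* The pooled logistic fit ignores participant-level clustering within a bin;
  clustering is instead respected by the resampling unit (whole
  participants).
* Censoring at the ROI end biases differences toward 0 when onsets fall near
  the window edge; widen the ROI or inspect the censored fraction.
* Cluster-mass permutation statistics and generalized additive time-course
  models are complementary approaches, not provided here.
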