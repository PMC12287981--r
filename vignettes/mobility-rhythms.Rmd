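---
title: "Mobility rhythms from duty-cycled GPS: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mobility rhythms from duty-cycled GPS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpsrhythms)
```

`gpsrhythms` implements a complete digital-phenotyping analysis for mood
disorders: from raw duty-cycled smartphone GPS fixes and daily ecological
momentary assessment (EMA) mood items, through trajectory preprocessing and
eight daily mobility features, to Fourier power spectra of feature rhythms
and the statistical models that relate mobility to depressed, manic,
fatigued, and irritable days in a healthy-control / bipolar (BP) /
major-depression (MDD) cohort. Because raw clinical GPS data cannot be
shared, the package ships a first-class synthetic cohort generator whose
outputs carry the statistical structure the analysis is designed to detect;
every downstream stage is exercised and validated against it.

## The measurement model

A phone records its position at 1 Hz for a 60 s *on-cycle*, then sleeps for
a 600 s *off-cycle*. The long-run average is
`3600/(60+600) × 60 = 327.3` fixes per hour (`expected_fix_count()`), and
any single span containing a whole number of 660 s cycles matches that rate
exactly; an individual clock hour can deviate because the cycle does not
divide the hour. Each fix carries a reported accuracy; fixes worse than
50 m are discarded before any further processing.

Positions are averaged on a fixed 10-second grid anchored at local midnight
(the anchor is a convention; day-level features and the validity rule are
local-day quantities, and Taiwan — the emulated setting — has no daylight
saving). A grid bin with no fix is missing. Consecutive valid bins displaced
by more than √10 m form a *moving* step (≈0.32 m/s); the rule is stated as a
distance per 10 s, not a speed, and is applied to bin-to-bin displacement.
Steps touching a missing bin are *unknown*; a maximal unknown run flanked by
valid bins resolves to moving when the displacement across it, prorated to
any 6-minute span under a linear-motion assumption, reaches 75 m (for runs
shorter than 6 minutes this is simply the endpoint displacement). This
windowed rule is what classifies the 600 s duty-cycle gaps, so state
classification is performed once, on the observed bins.

Gaps are then filled for the position-dependent features: each interior run
of at most 60 minutes is linearly interpolated between its flanking bins,
plus a zero-mean Gaussian *bridge* (one draw per gap per completion, scaled
by a sine profile vanishing at the flanks, default sd = the GPS noise sd).
Ten completions are generated and features averaged across them. The bridge
form matters: independent per-bin jitter would masquerade as movement and
add phantom distance at every imputed step, while a smooth bridge perturbs
the gap trajectory as a whole and leaves the across-completion mean equal to
the linear interpolant. Longer and edge gaps are filled from a donor day
(same participant, same clock bins) when available, else left missing. A day
enters the analysis only when at least 6 of its 24 clock hours contain data.

## The eight features

For one participant-day, with positions in a per-participant equirectangular
projection (meters east/north of home):

* **LV** — `ln(var(x) + var(y) + ε)` over stationary bins, population
  variances, `ε = 1e-6 m²` so a perfectly still day is finite. Natural log
  is used throughout (the entropy is in nats for the same reason).
* **NC, entropy, homestay** — greedy sequential clustering of stationary
  bins: a bin joins the nearest centroid within 500 m, else opens a cluster;
  centroids are running dwell-weighted means. The greedy rule is
  deterministic and order-stable, which makes it testable bin-by-bin,
  unlike iterated k-means. Entropy is `−Σ pᵢ ln pᵢ` over cluster dwell
  shares; home is the cluster with maximal 00:00–06:00 dwell (the standard
  digital-phenotyping convention; falling back to total dwell), and
  homestay its dwell share.
* **TT** — moving seconds / (moving + stationary seconds). The denominator
  is observed classified time rather than 24 h, so the feature is robust to
  missingness.
* **TD, SM, SV** — sum of consecutive-valid-bin displacements; the per-step
  speed is displacement/10 s, with SM its mean and SV its population
  variance.

## Spectral analysis of feature rhythms

Daily sampling cannot represent a 1-day cycle (it sits exactly at the
Nyquist frequency), so spectral input series are hourly by default: per-hour
LV and dwell entropy, placed on a regular grid over a 28-day window (56- and
84-day windows are available), linearly interpolated across gaps, rejected
when more than 25% of grid points are missing, and mean-removed. The plain
DFT is used with a rectangular taper (a Hann option exists); power is
`|X_k|²/N`, which makes the total over all bins equal the series sum of
squares (Parseval, asserted to 1e-9 relative in the tests). The DC bin is
excluded and candidate periods restricted to `[2·step, window/2]` —
resolvable and sampled at least twice.

Peaks are the `k = 5` highest-power *local maxima*, rank 1 the strongest;
exact power ties go to the longer period so output is deterministic. The
local-maximum requirement exists because an off-bin tone (e.g. a 9-day cycle
in a 28-day window, whose true frequency falls between the period-9.33 and
period-7 bins) leaks power into the neighbours of its nearest bin; those
shoulders describe the same periodic component and must not occupy two of
the five ranks.

Group consensus maps each peak to the integer day `d = round(period)`,
provided `d ≥ 1` and the period lies within 25% of `d`. Both guards protect
the integer-day consensus from aliasing: without them, every sub-1.5-day
noise peak in a 28-day hourly spectrum would round to "1 day" (38 of the
335 bins do), and an aperiodic group would spuriously share a 1-day cycle.
A period flagged *majority* is carried by strictly more than half of the
group's participants; the summed rank (lower = stronger) accompanies each
count.

## The statistical layer

Mood-day rates are the percentage of scored person-days with an EMA item
above 1 (1 = "not at all"). Group comparisons use Kruskal–Wallis (wrapping
`stats::kruskal.test`, with H defined as 0 under complete ties) and a
Mann–Whitney U with mid-ranks, tie-corrected normal-approximation two-sided
p (no continuity correction), and pooled mean ranks — the form in which
group spectral-power comparisons are reported. At the in-scope group sizes
(12 vs 19) the normal approximation is the conventional choice.

The person-day logistic model regresses depressed-day status on sex, age,
an employee-or-student indicator, and the mobility features retained by
iterative VIF pruning (drop the largest VIF until all ≤ 3; infinite VIFs
from exact collinearity go first), in all-days, weekday (Mon–Fri), and
weekend strata. Repeated person-days are deliberately treated as independent
— that is the analysis being emulated, and its acknowledged weakness — with
an optional participant-clustered (sandwich) variance for sensitivity
checks. Wald 95% CIs are reported throughout; TT and homestay enter as
fractions, which is why their per-unit ORs are numerically extreme.
Window-level models regress an EMA status flag (any mood day in the window)
on the maximum spectral power under four nested covariate sets (none;
age+sex; +work; +antidepressants). Because the scale of raw power is
arbitrary, the OR per predictor SD is attached alongside the per-unit OR.
The Fisher-z sample-size helper implements
`n = ⌈((z₁₋α/2 + z_power)/atanh r)²⌉ + 3` (38 at r = 0.5, α = .05,
power = .90).

## What the generator emulates — and what it does not

The generator has two tiers. The **trajectory tier** emits what the phone
would record: a continuous within-day path over home/work/other clusters
(pairwise ≥ 200 m apart), sampled through the duty cycle, with isotropic
Gaussian noise (default sd 3 m, a typical open-sky smartphone figure chosen
so that 10-s averaged positions sit comfortably inside the √10 m state
threshold) and a lognormal reported accuracy calibrated so 5% of fixes
exceed the 50 m filter. Mood couples multiplicatively into behaviour: each
EMA depression point above 1 multiplies the expected excursion count, the
away-time fraction, and the novel-place probability by `(1 − effect)`
(defaults 0.75, 0.75, 0.8), so depressed days have lower LV, TT, and entropy
*by construction*. The group dynamics modulate the same latent scale: BP
mood and mobility oscillate as a sum of sinusoids at the configured periods
(default 1, 4, 9 days, amplitude 1) with participant-specific phases; MDD
follows a bounded mean-reverting walk (AR(1), φ = 0.9, stationary sd =
`mdd_amplitude`); HC carry noise only. EMA items are monotone
discretizations of item-specific latents at fixed cut-points placed so the
configured mood-day rates hold in expectation — 9% of control days and 44%
of patient days depressed, 48% of BP days manic, the cohort rates the
analysis assumes — with mania anti-phase to depression. A dispersion knob
adds per-participant logit-scale heterogeneity to these rates; it defaults
to 0 because no cohort-level value is available to anchor it.

The **feature tier** (`simulate_feature_hours()`, `simulate_person_days()`,
`simulate_coupled_series()`) emits hourly feature series and person-day
rows directly from the same latent processes, bypassing GPS emission. The
statistical property studies — consensus recovery over 20 cohorts,
rejection rates over hundreds of replicates, regression recovery at
thousands of person-days — use this tier; pushing every replicate through
the 1 Hz trajectory chain would multiply compute by orders of magnitude
without changing what is being tested, since the trajectory chain itself is
validated separately (including the construction check that depressed days
depress the features). In the hourly tier "aperiodic" is implemented as a
spectrally flat fluctuation: an aperiodic group must have no preferred
period, and a slow red-spectrum process would concentrate its power at the
longest resolvable periods and manufacture spurious long-period consensus.

Features of real data the generator deliberately omits: device and vendor
heterogeneity, battery- or behaviour-dependent missingness (missingness is
uniform per day/hour), international travel, and — in the hourly feature
tier — the universal circadian home/away cycle, which in real data gives
*every* participant a strong 1-day spectral peak (the trajectory tier does
produce it, as the pipeline's consensus tables show). Passing tests
therefore demonstrate that the estimators recover what the model plants,
not that real cohorts behave like the model.

## Problem sizes and numerical conventions

The shipped tests run the cohort calibration at ≥1000 person-days per
group, oracle equivalences at 100 random instances per estimator, consensus
recovery over 20 cohorts of 12 + 19 participants (28-day hourly windows),
separation power over 200 replicates with a 1000-replicate null
calibration, regression recovery at ~3700 weekday person-days with a
200-replicate null coverage check, and the timescale comparison over 50
cohorts — sizes chosen to put Monte-Carlo error well inside the asserted
margins while keeping a full run in tens of seconds. Degenerate inputs have
defined behaviour throughout: a perfectly still day yields `LV = ln ε`,
entropy 0, homestay 1, TT 0; complete ties give H = 0; complete separation
in a logistic fit raises an error naming the separating term; a
zero-variance correlation is flagged undefined rather than thrown;
uninterpolatable days (fewer than two valid bins) and all-zero dwell are
errors.

## Known limitations

Equirectangular projection is adequate at city scale but not for
participants spanning hundreds of kilometers. The greedy clusterer's
centroids can drift along elongated visit patterns. Homestay depends on a
00:00–06:00 heuristic that misidentifies night-shift workers' homes.
Window-level mood status ("any mood day in the window") is one of several
defensible definitions. And the person-day models inherit the
independence-across-days assumption of the analysis they reproduce; the
cluster-robust option quantifies, but does not remove, that weakness.
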