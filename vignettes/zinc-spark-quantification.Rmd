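---
title: "Quantifying zinc sparks and their link to embryo outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying zinc sparks and their link to embryo outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zincspark)
```

## The measurement problem

At activation — whether triggered by a calcium ionophore or by a
fertilizing sperm — a mammalian egg expels billions of zinc ions in one or
a few exocytotic bursts. With a cell-impermeant zinc dye in the medium,
each burst appears as a transient rise of extracellular fluorescence
concentrated at the cell periphery, where the zinc-loaded cortical
vesicles sit. The working hypothesis this package operationalizes is that
the size of this "zinc spark" carries information about the zygote's
developmental potential, so that spark profiles measured within minutes of
activation could rank embryos days before morphology can.

The pipeline has four stages, each exposed as ordinary functions and
driven by the numbered scripts under `analysis/`:

1. **Simulation** (`simulate_trace()`, `simulate_image_series()`,
   `simulate_cohort()`, `simulate_nucleus_stack()`) — synthetic data with
   recorded ground truth, standing in for the unreleased imaging data.
2. **ROI extraction** (`segment_egg()`, `make_ring()`, `extract_trace()`)
   — from image stacks to per-egg intensity traces.
3. **Spark profiling** (`normalize_trace()`, `detect_sparks()`,
   `profile_event()`) — from traces to per-event parameters.
4. **Cohort statistics** (`assign_groups()`, `normalize_to_reference()`,
   `correlate_amp_cells()`, `percentile_select()`) — from events and
   outcomes to the group comparisons, the amplitude–cell-number
   correlation, and the prospective-selection contrast.

## Trace model and normalization

A recording is `n_frames` samples at a fixed `frame_interval_s` (defaults
75 frames at 4 s — five minutes of acquisition, matching the standard
ionophore-activation protocol). Fluorescence is normalized to
$F/F_0$, where $F_0$ is the mean of the **first five** raw measurements,
taken before any spark. After normalization the mean of the first five
samples is exactly 1, and all event parameters are expressed in $F/F_0$
units, which cancels illumination and dye-concentration scale: every
profile parameter is invariant to multiplying the raw trace by a positive
constant (tested exactly).

Because $F_0$ must precede the spark, a profile whose first event's rise
reaches back into the five-frame baseline window is flagged
`invalid_baseline` rather than silently accepted or re-anchored. The flag
back-tracks the detected start through every preceding frame still above
the event-end threshold; a start-threshold test alone could never fire
inside the window, since no sample of a five-point window can exceed its
own mean by more than $4/\sqrt{5} \approx 1.8$ of its SD while the start
threshold sits at 3 SD.

## Spark shape

Each spark contributes an excess with a saturating rise times an
exponential decay,

$$ e(s) \propto \left(1 - e^{-s/\tau_r}\right) e^{-s/\tau_d}, \qquad s = t - t_{\text{onset}} \ge 0 ,$$

rescaled to unit maximum, so the `spark_amplitudes` parameter *is* the
realized peak height in $F/F_0 - 1$ units. The unnormalized product form
peaks below 1 at a height that depends on $\tau_r/\tau_d$; leaving it
unscaled would make "amplitude" mean different things at different shape
settings, and would break the correspondence between the generator's
amplitude, the profiler's recovered amplitude, and the outcome model's
amplitude covariate. The peak occurs
$\tau_r \log(1 + \tau_d/\tau_r)$ after onset (≈ 9.6 s at the defaults
$\tau_r = 4$ s, $\tau_d = 40$ s), so 4-second sampling undershoots the
continuous peak by at most ~1.5%.

Defaults: baseline 1000 counts; Gaussian read noise SD 20 counts (so a
typical amplitude-2 spark has a peak-to-noise ratio of ~100, and even an
amplitude-0.2 spark stays at 10); optional Poisson shot noise; linear
photobleaching (fraction of signal per frame) as the simplest baseline
drift — real bleaching is closer to exponential, but over 75 frames the
distinction is second-order and the linear form makes the stressor's size
explicit.

## Event detection and the four spark parameters

Detection is threshold-crossing against the pre-spark baseline of the
normalized trace. The baseline noise $\sigma_b$ is the SD of the first
five normalized values, floored by a robust whole-trace estimate
(median absolute successive difference divided by
$\sqrt{2}\,\Phi^{-1}(0.75)$) and by a small $\varepsilon$ (default
$10^{-6}$) so noiseless traces remain detectable. The robust floor matters:
a five-sample SD underestimates the noise often enough that two-frame
noise runs would otherwise be declared events. An event starts at the
first of at least `min_rise_frames = 2` consecutive frames above
$1 + 3\sigma_b$, ends at the first post-peak frame below $1 + \sigma_b$,
and is right-censored (flagged, not dropped) if the trace ends first.
All three multipliers are exposed as arguments.

Per event, on the normalized trace:

* **amplitude** — maximum peak height above baseline,
  $\max(F/F_0) - 1$ (a sparkless trace scores 0; the alternative
  "absolute max $F/F_0$" convention differs by exactly 1);
* **integrated intensity** — trapezoidal area under $F/F_0 - 1$ across
  the event window, negative excursions clipped at 0, in
  $(F/F_0-1)\cdot$seconds;
* **duration** — end minus start, seconds;
* **rate of rise** — amplitude divided by the rising time (peak minus
  start); reported missing when the peak falls on the window's first
  frame. The identity rate-of-rise × rising-time = amplitude holds
  exactly by construction and is asserted over seeded cohorts.

Plateau peaks resolve to the earlier frame. The trapezoid rule is exact
for the piecewise-linear interpolant of the samples, which is why the
suite checks it against a 100×-oversampled Riemann sum at 0.1%.

When two sparks are closer than the decay tail's return below the end
threshold, they merge into one detected event whose amplitude is the
envelope maximum. Within a five-minute window and $\tau_d = 40$ s this
happens for most simulated multi-spark eggs; analyses that key on the
*first* spark are therefore read as "first detected event" — the same
ambiguity a manual scorer faces on overlapping events.

## Image path

`simulate_image_series()` renders the extracellular-dye geometry: bright
background at the dye baseline, a dye-excluding cell interior at 25% of
baseline, and spark excess emitted from an annulus at the egg perimeter
(optionally one hemisphere, mimicking cortical polarization opposite the
sperm entry point). Because every emitting pixel carries the same
temporal excess, the ring-ROI mean trace equals the direct trace
simulation exactly at zero noise — the closure test for the image path.

ROI membership is decided by the pixel-center radial inequality, half-open
($r_{\text{in}} \le d < r_{\text{out}}$), which makes the interior disk
and its perimeter ring exactly disjoint. Ring thickness defaults to 5 px
and is by convention identical for all eggs of a run. `segment_egg()`
automates the manual ROI step: Otsu threshold on the temporal-mean frame,
foreground taken as the class not dominating the image border (so the
rule is agnostic to whether the egg is dark-on-bright, as in the zinc
channel, or bright-on-dark), largest connected component, centroid and
equivalent-area radius. Hand-drawn ROIs can be supplied via CSV instead.

Nucleus counting thresholds a z-stack at half its maximum (relative, so
counts are scale-invariant), labels 26-connected 3D components, and
discards components under 27 voxels. The simulator guarantees countable
ground truth by enforcing a 4σ center separation, which keeps half-max
surfaces of adjacent nuclei disjoint; overlapping-nucleus resolution is
out of scope.

## Cohort model

`simulate_cohort()` is a generative stand-in for the biology linking
sparks to outcome, with every link configurable:

* spark presence with probability `p_spark` (default 0.85); multi-spark
  (2–4 events) with probability 7/42, the observed multi-spark fraction
  among fertilized eggs;
* first-spark amplitude log-normal (median 2, log-SD 0.4 by default) —
  the across-egg amplitude distribution is unreported anywhere, so this
  is a modelling choice for a positive right-skewed quantity, not an
  inference;
* onset latency normal around 128 s, the one directly observed
  sperm-entry-to-spark latency;
* sparkless eggs unactivated with probability 0.8, otherwise
  non-blastocyst;
* sparked eggs reach blastocyst with probability
  $\mathrm{logit}^{-1}(\beta_0 + \beta_1 a)$ (defaults $\beta_0 = -3$,
  $\beta_1 = 1$ per amplitude unit), otherwise arrest as morula with
  probability 0.5 or earlier;
* morulae and blastocysts draw cell counts
  $\alpha_0 + \alpha_1 a + \mathcal{N}(0, \sigma_c)$ (defaults 10 + 12a,
  $\sigma_c = 4$), rounded to positive integers — placing morulae near 30
  and blastocysts near 50 cells at typical amplitudes, the range reported
  for imaged embryos, versus >80 cells for non-imaged controls.

Integer rounding can tie two close amplitudes to one count, so the
"noiseless ⇒ rank-perfect" property is exact only when the slope is steep
relative to the rounding granularity; the suite tests it in that regime
and asserts monotonicity throughout.

The run seed expands into per-egg substreams
(`seed + 7919 · egg index`, mod $2^{31}-1$), so enlarging a cohort never
perturbs earlier eggs — a property the suite checks byte-for-byte. All
randomness lives in the simulators; every analysis stage is
deterministic.

## Cohort statistics

Grouping follows the two analysis modes: `collapsed` (unactivated /
non-blastocyst / blastocyst, morulae counted as non-blastocyst) for the
parameter comparisons, `staged` (morula kept distinct) for cell-number
analyses. Group means are displayed relative to the non-blastocyst
reference (its normalized mean is exactly 1; SEMs scale identically), and
compared by Welch's t by default — pooled t, one-way ANOVA and chi-square
(no continuity correction) are available behind the same interface.

Z scores use the sample SD ($n-1$); the amplitude–cell-number association
is the Spearman rank correlation (average ranks on ties) plus an OLS line
on the z-scored pairs. Since ranks are invariant under the z-transform,
standardization affects only the displayed regression, never the
correlation — asserted exactly in the suite.

Prospective selection splits sparked eggs at the median first-spark
amplitude. Eggs exactly at the median go to the bottom arm — the
conservative direction for the claim that the top arm does better —
with the tie rule configurable. Arms are compared by blastocyst rate,
their ratio, and a 2×2 chi-square.

## What the simulations do and do not show

The generator reproduces the *structure* of the experiment: acquisition
timing, cortical emission geometry, decaying-dye baselines, spark
kinetics with separately tunable rise and decay, outcome labels with a
tunable amplitude dependence, and cell counts tied to amplitude. It does
not model optics (no PSF), egg-to-egg geometry variation beyond position
and radius, calcium–zinc coupling, sperm dynamics, or 3D embryo
structure. Green tests therefore certify the measurement chain —
normalization, detection, parameter recovery (within 10% amplitude and
one frame of onset in ≥95% of traces at the default noise), and the
statistical machinery — under a faithful-but-idealized forward model;
they cannot certify biological effect sizes, which in the simulations are
whatever the outcome-model parameters make them.

Problem sizes used by the default test and acceptance runs — 200-trace
recovery sweeps, cohorts of 500 over 10 seeds, one 5000-egg marginal
check, 128×128×75 image stacks and 96×96×24 nucleus stacks — were chosen
as the smallest sizes at which the Monte-Carlo properties under test are
stable.

## Known limitations

* Detection is single-threshold; overlapping sparks merge (see above)
  and sub-threshold sparks vanish rather than degrade gracefully.
* The baseline window is fixed at the first five frames; recordings that
  begin mid-event are flagged, not rescued.
* `segment_egg()` assumes one egg per field and a roughly circular
  cross-section; the returned radius is the equivalent-area radius.
* Durations of events that outlast the recording are right-censored and
  flagged; downstream comparisons use them as-is, which biases long-event
  statistics low — matching what a bounded imaging window measures.
* The fold-change of the selection arms depends strongly on the logistic
  slope and the amplitude distribution; the defaults make the direction,
  not the magnitude, of the published contrast the reproducible claim.
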