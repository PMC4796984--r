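# zincspark

Quantification of **zinc sparks** — the burst-like exocytotic release of
zinc that mammalian eggs mount at activation — from fluorescence
time-lapse recordings, and the cohort statistics linking spark profiles
to preimplantation development. The package is aimed at people analyzing
(or simulating) egg-activation imaging: it turns a multi-page TIFF stack
or a per-egg intensity trace into per-event spark parameters, and a table
of eggs with developmental outcomes into the standard retrospective and
prospective analyses.

## The quantities at the core

A trace is normalized to $F/F_0$ with $F_0$ = mean of the first five
measurements, taken before the spark. Each detected event is summarized
by four parameters:

| parameter | definition | units |
|---|---|---|
| amplitude $a$ | $\max(F/F_0) - 1$ over the event | $F/F_0 - 1$ |
| integrated intensity | $\int (F/F_0 - 1)\,dt$ (trapezoid, clipped at 0) | $(F/F_0-1)\cdot$s |
| duration | event end − start | s |
| rate of rise | $a \,/\, (t_{\text{peak}} - t_{\text{start}})$ | s$^{-1}$ |

Cohort analyses: group means relative to the non-blastocyst reference
(Welch's t / ANOVA / chi-square), the Spearman correlation between
first-spark amplitude and embryo total cell number displayed on Z scores
$(x-\bar x)/\mathrm{SD}$, and a prospective median split of eggs by
amplitude with arm-wise blastocyst rates. Simulators for traces, image
stacks, outcome-labelled cohorts and nucleus z-stacks provide ground
truth for every stage; see the methods vignette
(`vignettes/zinc-spark-quantification.Rmd`) for the models and the
design choices.

## Worked example

The numbered drivers under `analysis/` run the whole chain on a simulated
cohort of 200 ionophore-activated eggs (seed 20260922) and write their
tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_profile_sparks.R
Rscript analysis/03_cohort_statistics.R
Rscript analysis/04_image_path.R
```

Output of stage 3 on that cohort:

```
amplitude              blastocyst/non-blastocyst = 1.26 (Welch t, p = 0.0036)
integrated_intensity   blastocyst/non-blastocyst = 1.33 (Welch t, p = 0.0069)
duration_s             blastocyst/non-blastocyst = 1.03 (Welch t, p = 0.23)
rate_of_rise           blastocyst/non-blastocyst = 1.17 (Welch t, p = 0.099)
amplitude vs cell number: Spearman R = 0.9057 (n = 122); z-score fit slope 0.930, intercept 2.59e-17
median split at amplitude 2.09: top 36/88 (41%) vs bottom 19/89 (21%) blastocysts, fold 1.92 (chi2 p = 0.00493)
```

Reading it: embryos that reached the blastocyst stage had, on average,
26% larger spark amplitudes and 33% larger integrated zinc release than
embryos that stalled (means scaled so the non-blastocyst group is 1);
first-spark amplitude ranks embryo cell number almost perfectly
(Spearman R ≈ 0.91 on this draw); and pre-selecting the top-half
amplitudes roughly doubles the blastocyst rate relative to the bottom
half. Stage 4 closes the image path: a zero-parameter re-analysis of a
simulated TIFF stack recovers the egg (center exact, radius 30.0 px),
the injected spark (amplitude 2.47 of 2.5 injected, onset 132 s of
128 s), and exact nucleus counts (30 and 80) from z-stacks.

The same chain in code:

```r
library(zincspark)
co <- simulate_cohort(200, seed = 1)
profiles <- lapply(co$traces, profile_trace)
grouped <- assign_groups(co$records, profiles)
percentile_select(grouped[!is.na(grouped$amplitude), ])
```

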