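# gpsrhythms

Digital phenotyping of mobility rhythms from duty-cycled smartphone GPS, for
researchers studying mood disorders with passive sensing. The package
implements, end to end and on fully synthetic data, the analysis chain that
links GPS-derived mobility to daily self-reported mood in a three-group
cohort — healthy controls (HC), bipolar disorder (BP), and major depressive
disorder (MDD):

1. **Synthetic cohort generator** — duty-cycled GPS trajectories (60 s
   on-cycle at 1 Hz, 600 s off-cycle, ≈327 fixes/hour) over per-participant
   home/work/other location clusters, plus daily four-item ecological
   momentary assessment (EMA) mood series (depression, mania, fatigue,
   irritability, each 1–5). Depressed days shrink the excursion count,
   away-time fraction, and place diversity multiplicatively; BP participants
   carry sinusoidal amplitude cycles (1-, 4-, 9-day by default), MDD
   participants an aperiodic fluctuation.
2. **Preprocessing** — 50 m accuracy filter, 10-second position averaging,
   stationary/moving segmentation (movement when a 10-s displacement exceeds
   √10 m; data gaps resolved as movement when the displacement prorated to
   any 6-minute span reaches 75 m), stochastic linear-interpolation gap
   imputation (10 completions), a 6-valid-hours/day inclusion rule, and
   daily EMA resolution (12:45 prompt, 17:00 fallback).
3. **Mobility features** — per participant-day: location variance
   `LV = ln(var(x) + var(y))`, speed mean SM and variance SV, number of
   location clusters NC (greedy 500 m clustering), Shannon entropy of
   cluster dwell, homestay, transition time TT (moving fraction of
   classified time), and total distance TD.
4. **Spectral analysis** — hourly feature series → discrete Fourier power
   spectra (power `|X_k|²/N`, period = 1/frequency), top-5 ranked peaks per
   participant-window, and group consensus tables flagging integer-day
   periods carried by more than half of a group.
5. **Inference** — mood-fluctuation day rates, Kruskal–Wallis and
   Mann–Whitney tests (with pooled mean ranks), feature–mood correlations by
   timescale, iterative VIF > 3 pruning, person-day logistic models of
   depressed-day status on mobility (weekday/weekend strata), logistic
   models of affective status on maximum spectral power (four nested
   covariate sets), and the Fisher-z sample-size formula
   `n = ⌈((z₁₋α/2 + z_power)/atanh r)²⌉ + 3`.

Everything is deterministic given one root seed, which is split
hierarchically per participant, day, and stage.

## Worked example

```r
library(gpsrhythms)

cfg <- cohort_config(n_hc = 1, n_bp = 1, n_mdd = 1, n_days = 28, seed = 42)
coh <- generate_cohort(cfg)
p     <- coh[coh$group == "BP", ]
moods <- simulate_mood_series(p, cfg)
fixes <- simulate_day_trajectory(p, moods[4, ], cfg)
nrow(fixes)
#> [1] 7560

day_start <- as.numeric(as.POSIXct(moods$date[4], tz = "UTC")) - 8 * 3600
day <- process_day(fixes, p$home_lat, p$home_lon, day_start, seed = 1)
round(day$features[, 1:8], 3)
#>       lv  sm    sv nc entropy homestay    tt       td
#> 1 10.437 0.1 0.117  2   0.005    0.999 0.109 8160.815
```

The day delivered ~7560 fixes (a little under the ideal 24 × 327 because two
hours were lost to missingness), and preprocessing turned them into the
eight features: the participant visited 2 significant places, spent 99.9% of
stationary dwell at home, moved for 10.9% of classified time, and covered
8.2 km. The spectral layer recovers the injected mobility cycles of a
BP-like participant from 28 days of hourly location variance:

```r
h <- simulate_feature_hours("BP", n_days = 28, seed = 42)
window_spectral_summary(h$t_days, h$lv, window_days = 28)
#>   rank period_days frequency  power
#> 1    1        1.00      1.00 179.33
#> 2    2        9.33      0.11 168.59
#> 3    3        4.00      0.25 164.16
#> 4    4        5.60      0.18   2.13
#> 5    5        0.15      6.50   1.40
```

The three dominant peaks sit at the injected 1-, 4-, and 9-day cycles (9
days is observed at the nearest 28-day-window frequency bin, period 28/3 ≈
9.33 d); the 4th and 5th peaks are two orders of magnitude weaker noise.
`cohort_period_consensus()` aggregates such peak sets into the group-level
consensus table, and `fit_daylevel_logistic()` / `fit_spectrum_logistic()`
run the mood-status models.

The full pipeline (simulate → preprocess → features → spectral → analyze)
runs from one config:

```r
run_pipeline(default_config(), out_dir = "out")   # or inst/cli/gpsrhythms.R
```

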