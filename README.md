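# gazeindex

Quantifying how people visually navigate a screen: velocity-threshold gaze
event classification, a per-participant metric suite built around the
**Gaze Index**, and cohort-level nonparametric group comparisons — plus a
calibrated synthetic gaze-stream generator so the whole pipeline runs and
is testable without access to raw eye-tracker recordings.

The package is written for behavioral and clinical-informatics researchers
analyzing monitor-mounted eye-tracker exports (timestamp, x, y, validity)
from screen-based tasks such as electronic health record review.

## The model

Gaze samples are segmented by the I-VT rule with a short-dwell extension.
With pixel pitch *p* (cm/px) and viewing distance *D* (65 cm default), the
two-point angular velocity of an inter-sample interval with pixel
displacement *d* over Δt is

    ω = 2·atan(d·p / 2D) / Δt        [deg/s]

Intervals with ω > 30 deg/s are saccadic. Below-threshold runs longer than
60 ms are **fixations** ("staring"); runs of at most 60 ms are
**microfixations**, the brief dwells inside reading-like
saccade–microfixation chains ("scanning"). Runs touching invalid samples
are **off-screen** episodes. The Gaze Index summarizes the balance of the
two strategies:

    GI = Σ fixation time / (Σ saccade time + Σ microfixation time)

GI < 1: superscanner; 1–3: scanner; 3–5: starer; > 5: superstarer. Because
it is a ratio of two portions of screen time, GI is independent of how long
a participant looked at the screen. Group differences are tested with the
two-sided Mann–Whitney U test (min-U convention, exact for small tie-free
samples), with odds ratios at the GI extremes and a Monte-Carlo
Kolmogorov–Smirnov (Lilliefors) normality check.

## Worked example

Simulate one 10-minute recording from the default female behavioral
profile, classify it, and reduce it to participant-level metrics:

```r
library(gazeindex)

profiles <- default_profiles()          # calibrated female/male phenotypes
stream <- generate_stream(profiles$female, seed = 1)
stream
#> <gaze_stream> participant female: 18001 samples, 600.0 s span, 45% valid

events <- classify_events(stream, classifier_params())   # 30 deg/s, 60 ms
events
#> <event_sequence> participant female: 3263 events (fixation=661,
#>   microfixation=940, saccade=1600, offscreen=62), span 600.0 s

compute_metrics(events, stream)
#> screen_time_fraction  0.44      # 44% of the task spent on screen
#> fixations_per_min     149.51
#> mean_fixation_ms      200.71    # staring episodes average ~200 ms
#> mean_interfixation_px 130.49
#> saccade_px_per_min    33880.20  # saccadic travel per screen-minute
#> saccades_per_min      361.90
#> mean_saccade_ms       63.29
#> gaze_index            1.00      # equal staring and scanning
#> gi_category           "scanner"
```

This participant spent 44% of the task on screen and split that screen
time evenly between staring and scanning (GI ≈ 1), i.e. a scanner.

A full cohort run — simulate, classify, compare the sexes — is one call:

```r
res <- run_analysis(spec = cohort_spec(n_female = 10, n_male = 10, seed = 1))
res$comparison$comparisons[, c("metric", "mean_female", "mean_male", "p_value")]
#>                  metric mean_female mean_male p_value
#> 1  screen_time_fraction    4.42e-01  5.82e-01 0.00131
#> 3      mean_fixation_ms    2.08e+02  2.37e+02 0.21229
#> 6      saccades_per_min    3.28e+02  2.35e+02 0.05390
#> 8            gaze_index    3.01e+00  4.35e+00 0.30749
#> ...
res$gi_summary
#>   gi_min  gi_max gi_mean n_above_3 n_below_3 n_below_1 n_above_5
#> 0.116417 7.43936 3.67699        11         9         4         8
```

At n = 10 per group only the largest effect (screen-time fraction) is
significant; the default 46 + 47 cohort has the calibrated power for the
fixation-duration difference as well. `run_analysis()` also accepts
`input_dir` with real delimited exports (`t_ms,x_px,y_px[,valid]` per
participant plus a `cohort.csv` with sex labels) instead of simulation,
and writes tidy CSV tables plus a JSON run manifest when `output_dir` is
given. A thin command-line wrapper is available at
`inst/scripts/run_pipeline.R`.

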