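# spindletraj

Sleep spindles — brief 10–16 Hz bursts of N2 sleep EEG generated by the
thalamocortical network — are candidate biomarkers of brain maturation:
their density, frequency, power, and fast-spindle fraction change
systematically between childhood and early adulthood, differently in
females and males and by pubertal stage. Studying those trajectories
requires three pieces that this package provides as one tested chain, for
sleep researchers and developmental biostatisticians:

1. **Spindle detection** on central derivations (C3/C4): a sliding-window
   spectral-ratio algorithm. Power *S* is the spectral power summed over
   10–16 Hz in a 1-s FFT window advancing every 0.2 s; its ratio to the
   30th percentile of power *S* within the surrounding 30-s epoch must
   exceed 3 for five consecutive windows, and the event must terminate
   (ratio < 1.5 or power *S* < 20% of peak, whichever threshold is crossed
   first) within 5 s. Candidates overlapping arousals, dominated by
   flanking α/β-band activity, or outside N2 are rejected. Outputs per
   subject: density (/min N2), mean peak frequency (Hz), mean peak power
   (µV²), and fast-spindle percent (peak ≥ 12 Hz).
2. **Absolute NREM σ power**: per 30-s epoch, 22 half-overlapping 2.56-s
   Hann windows give a 0.390625-Hz-resolution spectrum; σ power sums bins
   11.33–14.84 Hz (inclusive), averaged over artifact-free N2+N3 epochs and
   the two central channels, in µV².
3. **Maturational statistics**: covariate-adjusted polynomial age models
   (cubic → quadratic → linear ladder, highest significant term retained),
   predicted population mean curves with 95% CIs and ages of extrema,
   standardized piece-wise slopes (β_s = slope of outcome/SD), sex and
   Tanner-group least-squares-mean contrasts, longitudinal percent-change
   models `100·(follow-up − baseline)/baseline`, Pearson correlation
   matrices, and Lin's concordance ρ_c for reference-dialect agreement.

Because population PSG data cannot be shipped, the package includes a
seeded synthetic polysomnography generator (staged EEG with 1/f background
and ground-truth spindle events, contaminants, arousals, artifacts; EDF +
sidecar export) and a cohort simulator with known trajectory parameters, so
the whole chain is testable by parameter recovery.

## Worked example

```r
library(spindletraj)

# one simulated night segment (60 min staged sleep, seeded)
sim  <- simulate_sleep_eeg(eeg_sim_config(seed = 42))
grid <- epoch_grid(sim$recording, sim$hypnogram, sim$annotations)

ev <- detect_spindles(sim$recording, sim$hypnogram, sim$annotations)
summarize_metrics(ev, grid, c("C3-M2", "C4-M1"))
#>   channel n_events n2_minutes density mean_frequency mean_power fast_percent
#> 1   C3-M2      139         35    3.97           12.8        240         74.1
#> 2   C4-M1      139         35    3.97           12.8        242         73.4
#> 3 average      139         35    3.97           12.8        241         73.7
```

139 events in 35 minutes of N2 gives density 3.97/min against 141 embedded
ground-truth spindles (the generator's rate is 4/min); mean peak frequency
12.8 Hz with 74% fast spindles matches the 11–15 Hz generating band.

```r
sigma_power_analysis(sim$recording, sim$hypnogram, sim$annotations)
#>   channel sigma_power_uv2 n_epochs n_accepted percent_accepted
#> 3 average            12.2      100         83               83
```

σ power is 12.2 µV² over the 83% of NREM epochs that survive artifact
rejection (movement artifacts are simulated at 15/h).

```r
cohort <- simulate_cohort(cohort_sim_config(n_subjects = 500, seed = 42),
                          "cross_sectional")
fit <- fit_age_trajectory(cohort$table, "density")
fit
#> <trajectory_fit> density ~ age^2 (+6 covariates), R^2 = 0.545
locate_extrema(fit)
#> $age_at_min 6      $age_at_max 14.9
predict_mean_curve(fit, ages = c(6, 10, 15, 21))
#>   age  mean   lwr   upr
#> 1   6 2.871 2.764 2.978
#> 2  10 4.044 3.996 4.092
#> 3  15 4.559 4.506 4.612
#> 4  21 3.783 3.672 3.895
```

The ladder selects the quadratic (the generating degree), and the fitted
curve peaks at 14.9 years against a generating vertex of 15.2 — an
inverted-U density trajectory recovered with its covariate adjustment
(sex, race/ethnicity, BMI, AHI, disorder flag, PSG system).

A thin CLI over the same functions lives at `inst/cli/spindletraj.R`
(subcommands `simulate-eeg`, `simulate-cohort`, `detect-spindles`,
`sigma-power`, `fit-trajectories`, `run-all`); `run_pipeline()` drives the
whole chain from one YAML configuration and writes a reproducibility
manifest.

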