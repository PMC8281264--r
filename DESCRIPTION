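Package: spindletraj
Title: Sleep Spindle Detection, Sigma Power, and Maturational Trajectory
    Analysis for Pediatric Sleep EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects N2 sleep spindles in central EEG derivations with a
    sliding-window spectral-ratio algorithm, computes absolute NREM sigma
    power (11.33-14.84 Hz) from Hann-windowed per-epoch power spectra, and
    models maturational trajectories of spindle activity across childhood
    and adolescence: covariate-adjusted polynomial age models with
    data-driven degree selection, predicted mean curves with extrema ages,
    standardized piece-wise slopes, covariate-adjusted group contrasts
    (sex, pubertal stage), longitudinal percent-change models, Pearson
    correlation matrices, and Lin's concordance correlation. Includes a
    synthetic polysomnography generator (staged EEG with ground-truth
    spindle events, 1/f background, contaminants, and artifacts) and a
    cohort simulator with known trajectory parameters, plus EDF read/write
    support and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    emmeans,
    graphics,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
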