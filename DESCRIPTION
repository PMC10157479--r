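Package: amsacc
Title: Amplitude Spectrum Area Estimation from VF ECG During Chest Compressions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the amplitude spectrum area (AMSA) of
    ventricular-fibrillation ECG while chest compressions are ongoing.
    Provides a synthetic generator for VF waveforms and quasi-periodic
    compression artifacts with exact SNR-controlled mixing, the FFT-based
    AMSA statistic over the 2-48 Hz band, a compression-frequency-tracked
    harmonic adaptive canceller (normalized LMS) as a reference baseline,
    a from-scratch 1D convolutional network that regresses AMSA directly
    from corrupted segments, sliding-window continuous monitoring, and an
    evaluation suite (MAE, RMSE, PRD, Spearman correlation, Bland-Altman
    agreement, ROC/AUC with DeLong and Hanley-McNeil comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    signal,
    yaml,
    generics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    withr
Config/testthat/edition: 3
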