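# amsacc

Amplitude spectrum area (AMSA) estimation from ventricular-fibrillation
(VF) ECG **during uninterrupted chest compressions**.

AMSA is the sum of amplitude x frequency over the 2-48 Hz band of a VF
segment's spectrum,

```
AMSA = sum_{2 <= f_k <= 48} A(f_k) * f_k        [mV Hz]
```

with `A(f_k)` the single-sided amplitude spectrum of a Tukey-windowed
4-s segment at 250 Hz. It predicts defibrillation success and could guide
individualized resuscitation - if it could be computed while compressions
are ongoing. Chest-compression (CC) artifact occupies 0-20 Hz, on top of
the VF band, so the naive spectral sum taken during CPR is grossly
inflated. This package implements, on a fully synthetic but
distribution-matched test bench, the three estimators of interest to
resuscitation signal-processing researchers:

* **AMSA_FFT** (`amsa_fft()`) - the plain statistic;
* **AMSA_ADF** (`amsa_adf()`) - harmonic-model artifact cancellation
  driven by a compression reference channel (normalized LMS at the
  instantaneous compression frequency, 5 harmonics), then the statistic
  on the residual;
* **AMSA_CNN** (`build_cnn()` / `train_cnn()` / `predict_amsa()`) - a
  1-D convolutional network (blocks of conv - batch norm - leaky ReLU -
  max-pool, a global-pool block with dropout, and a 3-layer regression
  head; default W = 11 taps, N = 5 pooled blocks, C = 32 channels)
  regressing AMSA directly from the corrupted waveform, no reference
  channel needed. The network and its training (Adam on MSE, batch
  mini-batches, x8 symmetry augmentation) are implemented in-package
  with compiled inner loops.

Around these sit a synthetic VF / CC-artifact generator with exact
SNR-controlled mixing (`generate_vf()`, `generate_cc_artifact()`,
`mix_at_snr()`, `build_dataset()`), waveform I/O (CSV and WFDB format-16
records), subject-grouped cross-validation and hyperparameter grid
search, continuous 0.5-s-step monitoring (`amsa_monitor()`), and an
evaluation suite (MAE / RMSE / PRD / Spearman r / Bland-Altman /
ROC-AUC with DeLong and Hanley-McNeil comparisons).

## Worked example

```r
library(amsacc)

# a clean VF segment, a compression artifact, and their -6 dB mixture
vf  <- generate_vf(4, seed = 7)
art <- generate_cc_artifact(4, seed = 107)
svf <- mix_at_snr(vf, art$segment, snr_db = -6)

amsa_fft(vf)                      # true value:        7.99 mV Hz
amsa_fft(svf)                     # naive, corrupted: 12.96 mV Hz
amsa_adf(svf, art$reference)      # LMS-cancelled:     8.92 mV Hz
```

The naive estimate is inflated by ~60% because the artifact (here at
four times the VF power) pours amplitude into the 2-48 Hz band; the
adaptive filter removes most of the excess.
Training the CNN end to end and comparing all three on held-out
subjects:

```r
cfg <- experiment_config(seed = 1)           # 180 subjects, 2880 pairs,
ds  <- build_dataset(cfg)                    # SNR in {3, 0, -3, -6} dB
tr  <- ds[ds$split == "train", ]
te  <- ds[ds$split == "test", ]

mdl <- train_cnn(NULL, tr, train_config(batch_size = 256, epochs = 30,
                                        seed = 1))
res <- evaluate_estimators(te, mdl, cfg)
res[is.na(res$snr_db), c("estimator", "mae", "rmse", "prd", "spearman_r")]
#   estimator    mae  rmse   prd  spearman_r    (pooled over SNR levels)
#   amsa_fft   4.118 5.478 41.84       0.924
#   amsa_adf   1.139 1.872 14.30       0.963
#   amsa_cnn   0.666 0.942  7.19       0.986
```

(Numbers printed by the seed-1 run above, 576 held-out test pairs; the
training step takes about 7 minutes on one CPU. Exact values for other
seeds differ, but the error ordering FFT > ADF > CNN - most pronounced
at low SNR, where naive FFT MAE reaches 7.7 mV Hz at -6 dB while the
CNN stays below 0.8 - and the reverse ordering in rank correlation are
stable; the package's acceptance test asserts the CNN-vs-FFT comparison
per SNR level.) `amsa_monitor()` applies any of the estimators over a
sliding 4-s window every 0.5 s for trend display, and
`cmd_simulate()` / `cmd_train()` / `cmd_evaluate()` / `cmd_monitor()`
(or the `inst/cli/amsa.R` dispatcher) chain the stages on disk with
manifests for reproducibility.

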