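# shared fixtures: short deterministic waveforms and desk-scale configs

fs_default <- 250

sinusoid_segment <- function(freq, amp = 1, duration = 4, fs = fs_default,
                             phase = 0, role = "UNKNOWN") {
  t <- seq_len(round(duration * fs)) / fs
  ecg_segment(amp * sin(2 * pi * freq * t + phase), fs = fs, role = role)
}

# brute-force DFT amplitude-frequency sum; independent of stats::fft
amsa_oracle <- function(segment, f_lo = 2, f_hi = 48, tukey_alpha = 0.2) {
  x <- segment$samples
  n <- length(x)
  w <- amsacc:::tukey_window(n, tukey_alpha)
  xw <- x * w
  fs <- segment$fs
  total <- 0
  for (k in 0:floor(n / 2)) {
    fk <- k * fs / n
    if (fk < f_lo || fk > f_hi) next
    re <- sum(xw * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(xw * sin(-2 * pi * k * (0:(n - 1)) / n))
    amp <- 2 * sqrt(re^2 + im^2) / (n * mean(w))
    total <- total + amp * fk
  }
  total
}

# small synthetic dataset for model-level tests
tiny_dataset <- function(n_subjects = 10, pairs_per_snr = 1, seed = 11) {
  build_dataset(experiment_config(
    seed = seed, n_subjects = n_subjects, pairs_per_snr = pairs_per_snr,
    snr_levels = c(0, -6),
    split = c(train = 0.6, validation = 0.2, test = 0.2)
  ))
}

tiny_cnn <- function() {
  cnn_config(kernel_width = 5, n_pooled_blocks = 3, channels = 8,
             dropout = 0, fc_sizes = c(8, 1))
}

tiny_train <- function(epochs = 3, seed = 1) {
  train_config(batch_size = 64, epochs = epochs, seed = seed)
}
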