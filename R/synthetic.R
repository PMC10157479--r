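#' VF generator parameters
#'
#' Controls the synthetic ventricular-fibrillation generator: a sum of
#' narrowband frequency-modulated oscillators with slowly drifting
#' instantaneous frequency inside the dominant band, an amplitude-modulated
#' envelope, and a broadband noise floor. Adult VF concentrates its energy
#' below 18 Hz with a dominant peak typically between 3 and 7 Hz, and a
#' shockable segment has median peak-to-peak amplitude above 0.1 mV; the
#' defaults emulate that regime.
#'
#' @param dominant_freq_range Dominant-frequency band in Hz (within
#'   \[2, 18\]; default `c(3, 7)`).
#' @param n_components Number of narrowband oscillators (default 3).
#' @param freq_drift_sd Random-walk drift of each oscillator's
#'   instantaneous frequency, in Hz per sqrt(second), reflected at the
#'   band edges (default 3: the dominant frequency wanders across the
#'   band within a few seconds, keeping the waveform chaotic rather than
#'   periodic).
#' @param amplitude_pp_range Target peak-to-peak amplitude range in mV
#'   (default `c(0.2, 1.5)`).
#' @param noise_floor_db Broadband noise power relative to the oscillator
#'   power, in dB (default -20).
#' @return A `vf_gen_params` list.
#' @export
vf_gen_params <- function(dominant_freq_range = c(3, 7), n_components = 3,
                          freq_drift_sd = 3,
                          amplitude_pp_range = c(0.2, 1.5),
                          noise_floor_db = -20) {
  if (dominant_freq_range[1] < 2 || dominant_freq_range[2] > 18 ||
      diff(dominant_freq_range) < 0) {
    stop("dominant_freq_range must lie within [2, 18] Hz", call. = FALSE)
  }
  if (n_components < 1) stop("need at least one component", call. = FALSE)
  if (amplitude_pp_range[1] <= 0.1) {
    stop("amplitude_pp_range must keep peak-to-peak above the 0.1 mV ",
         "VF amplitude criterion", call. = FALSE)
  }
  structure(list(dominant_freq_range = dominant_freq_range,
                 n_components = n_components, freq_drift_sd = freq_drift_sd,
                 amplitude_pp_range = amplitude_pp_range,
                 noise_floor_db = noise_floor_db),
            class = "vf_gen_params")
}

#' Compression-artifact generator parameters
#'
#' Controls the quasi-periodic compression-artifact generator: concatenated
#' per-compression cycles, each a harmonic series at that cycle's
#' fundamental with power-law magnitudes and per-cycle lognormal magnitude
#' modulation (the heterogeneity seen in real CPR artifacts). The artifact
#' band is roughly 0-20 Hz with the fundamental at the compression rate.
#'
#' @param rate_range Compression rate range in compressions/min
#'   (within \[50, 200\]; default `c(80, 130)`).
#' @param cycle_jitter_cv Coefficient of variation of cycle lengths
#'   (default 0.05).
#' @param n_harmonics Harmonics per cycle (default 5).
#' @param harmonic_decay Power-law exponent of harmonic magnitudes
#'   (default 1, i.e. 1/k).
#' @param amplitude_pp_range Peak-to-peak amplitude range in mV
#'   (default `c(1, 5)`, exceeding typical VF amplitudes).
#' @param harmonic_mod_sd Lognormal sigma of the per-cycle magnitude
#'   modulation (default 0.2; 0 gives a stationary artifact).
#' @return A `cc_gen_params` list.
#' @export
cc_gen_params <- function(rate_range = c(80, 130), cycle_jitter_cv = 0.05,
                          n_harmonics = 5, harmonic_decay = 1,
                          amplitude_pp_range = c(1, 5),
                          harmonic_mod_sd = 0.2) {
  if (rate_range[1] < 50 || rate_range[2] > 200 || diff(rate_range) < 0) {
    stop("rate_range must lie within [50, 200] compressions/min",
         call. = FALSE)
  }
  if (n_harmonics < 1) stop("need at least one harmonic", call. = FALSE)
  structure(list(rate_range = rate_range, cycle_jitter_cv = cycle_jitter_cv,
                 n_harmonics = n_harmonics, harmonic_decay = harmonic_decay,
                 amplitude_pp_range = amplitude_pp_range,
                 harmonic_mod_sd = harmonic_mod_sd),
            class = "cc_gen_params")
}

# fold values into [lo, hi] by reflection at the boundaries
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

# 1/f-shaped broadband noise via spectral shaping
pink_noise <- function(n) {
  X <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) # two-sided frequency magnitude
  Re(stats::fft(X / sqrt(f), inverse = TRUE)) / n
}

#' Generate a synthetic VF segment
#'
#' @param duration Duration in seconds (>= 4).
#' @param params A [vf_gen_params()].
#' @param seed Integer seed; fixing it reproduces the waveform exactly.
#' @param fs Sampling rate in Hz (default 250).
#' @return An [ecg_segment] with role `UVF`.
#' @export
generate_vf <- function(duration = 4, params = vf_gen_params(), seed = NULL,
                        fs = 250) {
  if (duration < 4) stop("`duration` must be at least 4 s", call. = FALSE)
  if (!inherits(params, "vf_gen_params")) {
    stop("`params` must come from vf_gen_params()", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  lo <- params$dominant_freq_range[1]
  hi <- params$dominant_freq_range[2]
  sig <- numeric(n)
  for (j in seq_len(params$n_components)) {
    f_c <- stats::runif(1, lo, hi)
    drift <- cumsum(stats::rnorm(n, 0, params$freq_drift_sd / sqrt(fs)))
    # reflect the frequency walk at the band edges so it keeps wandering
    # instead of sticking to a boundary (which would produce a coherent,
    # organized-looking tone)
    f_inst <- reflect_into(f_c + drift, lo, hi)
    phi <- cumsum(f_inst) / fs
    env <- 1 + 0.4 * sin(2 * pi * stats::runif(1, 0.1, 0.4) * t +
                           stats::runif(1, 0, 2 * pi))
    sig <- sig + env * cos(2 * pi * phi + stats::runif(1, 0, 2 * pi)) / j
  }
  noise <- pink_noise(n)
  noise <- noise * sqrt(mean(sig^2) / mean(noise^2) *
                          10^(params$noise_floor_db / 10))
  sig <- sig + noise
  # calibrate the median per-1-s peak-to-peak amplitude (the quantity the
  # VF amplitude criterion is defined on) to the drawn target
  pp <- stats::runif(1, params$amplitude_pp_range[1],
                     params$amplitude_pp_range[2])
  sec <- split(sig, ceiling(seq_along(sig) / fs))
  med_pp <- stats::median(vapply(sec, function(s) diff(range(s)), 0))
  sig <- sig * pp / med_pp
  ecg_segment(sig, fs = fs, role = "UVF")
}

#' Generate a synthetic compression artifact
#'
#' @inheritParams generate_vf
#' @param params A [cc_gen_params()].
#' @return A list with `segment` (an [ecg_segment], role `CC`) and
#'   `reference` (the true [compression_reference]).
#' @export
generate_cc_artifact <- function(duration = 4, params = cc_gen_params(),
                                 seed = NULL, fs = 250) {
  if (duration < 4) stop("`duration` must be at least 4 s", call. = FALSE)
  if (!inherits(params, "cc_gen_params")) {
    stop("`params` must come from cc_gen_params()", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs)
  rate <- stats::runif(1, params$rate_range[1], params$rate_range[2])
  mean_cycle <- 60 / rate
  # draw cycle lengths until the segment is covered
  cyc <- numeric(0)
  while (sum(cyc) < duration + mean_cycle) {
    len <- mean_cycle * (1 + params$cycle_jitter_cv *
                           stats::rnorm(1))
    len <- min(max(len, 0.3), 1.2)
    cyc <- c(cyc, len)
  }
  onsets <- cumsum(c(0, cyc))
  # per-sample instantaneous fundamental = 1 / current cycle length
  cyc_id <- findInterval((seq_len(n) - 1) / fs, onsets,
                         rightmost.closed = FALSE)
  f0 <- 1 / cyc[cyc_id]
  phi <- cumsum(f0) / fs
  K <- params$n_harmonics
  mags <- (1 / seq_len(K))^params$harmonic_decay
  ph <- stats::runif(K, 0, 2 * pi)
  mod <- matrix(exp(stats::rnorm(length(cyc) * K, 0,
                                 params$harmonic_mod_sd)),
                nrow = length(cyc))
  sig <- numeric(n)
  for (k in seq_len(K)) {
    sig <- sig + mod[cyc_id, k] * mags[k] * cos(2 * pi * k * phi + ph[k])
  }
  pp <- stats::runif(1, params$amplitude_pp_range[1],
                     params$amplitude_pp_range[2])
  sig <- sig * pp / (max(sig) - min(sig))
  keep <- onsets <= (n - 1) / fs
  ref <- compression_reference(onsets[keep], fs = fs)
  list(segment = ecg_segment(sig, fs = fs, role = "CC"), reference = ref)
}

#' Mix a clean VF segment with an artifact at an exact SNR
#'
#' Scales the artifact by `g = sqrt((P_vf / P_cc) / 10^(snr_db / 10))` so
#' that the ratio of clean-signal power to scaled-artifact power equals the
#' requested level exactly (powers are mean squared amplitudes of the raw
#' segments).
#'
#' @param clean Uncorrupted VF [ecg_segment].
#' @param artifact Pure compression-artifact [ecg_segment] of the same
#'   length and rate.
#' @param snr_db Target signal-to-noise ratio in dB.
#' @return The corrupted [ecg_segment] (role `SVF`), with attributes
#'   `snr_db` and `gain`.
#' @export
mix_at_snr <- function(clean, artifact, snr_db) {
  stopifnot(is_ecg_segment(clean), is_ecg_segment(artifact))
  if (length(clean$samples) != length(artifact$samples) ||
      !isTRUE(all.equal(clean$fs, artifact$fs))) {
    stop("`clean` and `artifact` must share length and sampling rate",
         call. = FALSE)
  }
  p_vf <- mean(clean$samples^2)
  p_cc <- mean(artifact$samples^2)
  if (p_cc == 0) {
    stop("artifact has zero power; cannot scale to a finite SNR",
         call. = FALSE)
  }
  g <- sqrt((p_vf / p_cc) / 10^(snr_db / 10))
  out <- ecg_segment(clean$samples + g * artifact$samples, fs = clean$fs,
                     role = "SVF", subject_id = clean$subject_id,
                     t0 = clean$t0)
  attr(out, "snr_db") <- snr_db
  attr(out, "gain") <- g
  out
}

#' Amplitude-based rhythm checks
#'
#' `is_vf()` applies the shockable-VF amplitude criterion (median of the
#' per-second peak-to-peak amplitudes above 0.1 mV) together with a
#' disorganization surrogate: the normalized autocorrelation of the segment
#' may not have a peak above 0.75 at lags of 0.25-1.5 s, which an organized
#' QRS rhythm at 40-240 beats/min would produce. `is_asystole()` flags an
#' isoelectric segment with overall peak-to-peak amplitude below 0.1 mV.
#'
#' @param segment A 4-s [ecg_segment].
#' @return A single logical.
#' @export
is_vf <- function(segment) {
  stopifnot(is_ecg_segment(segment))
  x <- segment$samples
  fs <- segment$fs
  sec <- split(x, ceiling(seq_along(x) / fs))
  med_pp <- stats::median(vapply(sec, function(s) diff(range(s)), 0))
  if (med_pp <= 0.1) return(FALSE)
  ac <- stats::acf(x, lag.max = round(1.5 * fs), plot = FALSE)$acf[, 1, 1]
  lags <- seq_along(ac) - 1
  win <- lags >= round(0.25 * fs) & lags <= round(1.5 * fs)
  max(ac[win]) < 0.75
}

#' @rdname is_vf
#' @export
is_asystole <- function(segment) {
  stopifnot(is_ecg_segment(segment))
  diff(range(segment$samples)) < 0.1
}

#' Logistic shock-outcome model
#'
#' Links log-AMSA to the probability of defibrillation success (post-shock
#' organized rhythm above 40 beats/min sustained for at least 30 s):
#' `P(success) = plogis(beta0 + beta1 * log(amsa))`, `beta1 > 0`.
#'
#' @param beta0,beta1 Logistic coefficients (defaults -3 and 1.5).
#' @return An `outcome_model` list.
#' @export
outcome_model <- function(beta0 = -3, beta1 = 1.5) {
  if (beta1 < 0) stop("`beta1` must be non-negative: higher AMSA must not ",
                      "lower the success probability", call. = FALSE)
  structure(list(beta0 = beta0, beta1 = beta1), class = "outcome_model")
}

#' Simulate binary shock outcomes from AMSA values
#'
#' @param amsa_values Positive AMSA values in mV Hz.
#' @param model An [outcome_model()].
#' @param seed Integer seed.
#' @return Integer vector of 0/1 outcomes.
#' @export
simulate_shock_outcomes <- function(amsa_values, model = outcome_model(),
                                    seed = NULL) {
  if (any(!is.finite(amsa_values) | amsa_values <= 0)) {
    stop("all AMSA values must be positive and finite", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  p <- stats::plogis(model$beta0 + model$beta1 * log(amsa_values))
  stats::rbinom(length(p), 1, p)
}
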