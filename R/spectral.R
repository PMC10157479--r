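#' Spectral analysis configuration
#'
#' Settings for the AMSA statistic and the preprocessing high-pass filter.
#' AMSA is summed over the 2-48 Hz band of the single-sided amplitude
#' spectrum of a Tukey-windowed segment. The classic statistic reported in
#' the resuscitation literature (values of roughly 2-25 mV Hz for adult VF)
#' omits the bin-width factor; set `df_weighting = TRUE` to multiply the sum
#' by the bin width `fs/n` instead.
#'
#' @param f_lo,f_hi Band limits in Hz (defaults 2 and 48).
#' @param tukey_alpha Taper ratio of the Tukey window in \[0, 1\]
#'   (default 0.2; 0 is the rectangular limit).
#' @param df_weighting Multiply the amplitude-frequency sum by the bin width
#'   (default `FALSE`).
#' @param hp_cutoff High-pass cutoff in Hz for [highpass()] (default 0.5).
#' @return A `spectral_config` list.
#' @export
spectral_config <- function(f_lo = 2, f_hi = 48, tukey_alpha = 0.2,
                            df_weighting = FALSE, hp_cutoff = 0.5) {
  if (!(f_lo > 0 && f_hi > f_lo)) {
    stop("need 0 < f_lo < f_hi", call. = FALSE)
  }
  if (tukey_alpha < 0 || tukey_alpha > 1) {
    stop("`tukey_alpha` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(f_lo = f_lo, f_hi = f_hi, tukey_alpha = tukey_alpha,
                 df_weighting = df_weighting, hp_cutoff = hp_cutoff),
            class = "spectral_config")
}

# cosine-tapered (Tukey) window; alpha = 0 gives the rectangular window
tukey_window <- function(n, alpha) {
  if (alpha <= 0) return(rep(1, n))
  w <- rep(1, n)
  x <- (seq_len(n) - 1) / (n - 1)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * x[hi] / alpha - 2 / alpha + 1)))
  w
}

#' Baseline-drift removal high-pass filter
#'
#' Causal second-order Butterworth high-pass (default cutoff 0.5 Hz),
#' applied once in the forward direction as a real-time system would.
#'
#' @param segment An [ecg_segment].
#' @param cfg A [spectral_config()].
#' @return The filtered [ecg_segment].
#' @export
highpass <- function(segment, cfg = spectral_config()) {
  stopifnot(is_ecg_segment(segment))
  if (segment$fs <= 2 * cfg$hp_cutoff) {
    stop("sampling rate too low for the requested high-pass cutoff",
         call. = FALSE)
  }
  bt <- signal::butter(2, cfg$hp_cutoff / (segment$fs / 2), type = "high")
  y <- as.numeric(signal::filter(bt, segment$samples))
  ecg_segment(y, fs = segment$fs, role = segment$role,
              subject_id = segment$subject_id, t0 = segment$t0)
}

#' Amplitude spectrum area (AMSA) of a VF segment
#'
#' Computes the FFT-based AMSA statistic: the segment is Tukey-windowed, the
#' single-sided amplitude spectrum `A(f_k) = 2|X_k|/n` is compensated for
#' the window's coherent gain (so a unit sinusoid keeps unit amplitude), and
#' the products `A(f_k) * f_k` are summed over bins with
#' `f_lo <= f_k <= f_hi`. No zero padding is used, so a 4-s segment has a
#' 0.25 Hz bin width.
#'
#' @param segment An [ecg_segment] of at least 2 s (4 s in routine use).
#' @param cfg A [spectral_config()].
#' @return AMSA in mV Hz (non-negative scalar).
#' @examples
#' t <- seq(0, 4, by = 1 / 250)[-1]
#' s <- ecg_segment(sin(2 * pi * 5 * t))
#' amsa_fft(s, spectral_config(tukey_alpha = 0)) # ~ 5 mV Hz
#' @export
amsa_fft <- function(segment, cfg = spectral_config()) {
  stopifnot(is_ecg_segment(segment))
  n <- length(segment$samples)
  if (n / segment$fs < 2) {
    stop("segment shorter than 2 s: frequency resolution too coarse for AMSA",
         call. = FALSE)
  }
  w <- tukey_window(n, cfg$tukey_alpha)
  X <- stats::fft(segment$samples * w)
  f <- (seq_len(n) - 1) * segment$fs / n
  half <- seq_len(floor(n / 2) + 1)
  amp <- 2 * Mod(X[half]) / (n * mean(w))
  fk <- f[half]
  band <- fk >= cfg$f_lo & fk <= cfg$f_hi
  out <- sum(amp[band] * fk[band])
  if (cfg$df_weighting) out <- out * segment$fs / n
  out
}

#' Continuous AMSA monitoring over a sliding window
#'
#' Applies an AMSA estimator to successive 4-s windows of a longer recording
#' advanced by a fixed step (default 0.5 s), the cadence used for real-time
#' trend display during CPR.
#'
#' @param ecg An [ecg_segment] of duration >= `window`.
#' @param step Step between window starts, in seconds (> 0).
#' @param estimator Function mapping an [ecg_segment] to mV Hz
#'   (default [amsa_fft()]).
#' @param window Window length in seconds (default 4).
#' @param estimator_name Label stored in the output.
#' @return A tibble with columns `t` (window end time, s), `amsa` (mV Hz)
#'   and `estimator`. Empty when the record is shorter than one window.
#' @export
amsa_monitor <- function(ecg, step = 0.5, estimator = amsa_fft, window = 4,
                         estimator_name = "amsa_fft") {
  stopifnot(is_ecg_segment(ecg))
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  n <- length(ecg$samples)
  w <- round(window * ecg$fs)
  hop <- round(step * ecg$fs)
  if (n < w) {
    return(tibble::tibble(t = numeric(0), amsa = numeric(0),
                          estimator = character(0)))
  }
  starts <- seq(1, n - w + 1, by = hop)
  vals <- purrr::map_dbl(starts, function(s) {
    seg <- ecg_segment(ecg$samples[s:(s + w - 1)], fs = ecg$fs,
                       role = ecg$role, subject_id = ecg$subject_id,
                       t0 = ecg$t0 + (s - 1) / ecg$fs)
    estimator(seg)
  })
  tibble::tibble(t = ecg$t0 + (starts - 1 + w) / ecg$fs, amsa = vals,
                 estimator = estimator_name)
}

#' Trend plot for a monitoring series
#'
#' @param series Tibble as returned by [amsa_monitor()] (rows from several
#'   estimators may be concatenated).
#' @return A ggplot object.
#' @export
plot_monitor <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(x = .data$t, y = .data$amsa,
                                       colour = .data$estimator)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "AMSA (mV Hz)", colour = NULL) +
    ggplot2::theme_minimal()
}
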