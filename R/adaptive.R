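#' LMS canceller configuration
#'
#' The artifact model is a harmonic series at the instantaneous compression
#' frequency: `s_cc(i) = sum_k a_k(i) cos(2 pi k phi(i)) + b_k(i) sin(2 pi
#' k phi(i))`, with the phase `phi` accumulated sample-by-sample from the
#' compression-frequency track. The `2K` coefficients are adapted causally
#' by (normalized) least mean squares on the residual. With the default
#' five harmonics at typical compression rates the model spans the ~0-20 Hz
#' artifact band.
#'
#' @param n_harmonics Number of harmonics `K` (>= 1, default 5); `K` times
#'   the maximum compression frequency must stay below the Nyquist rate.
#' @param mu Adaptation step size (default 0.02). In normalized mode the
#'   per-sample update is `2 * mu * e(i) * u(i) / ||u(i)||^2` (Widrow's LMS
#'   convention with the step scaled by the instantaneous basis energy,
#'   which is exactly `K` for this basis); in raw mode the division by
#'   `||u||^2` is omitted.
#' @param normalized Use normalized LMS (default `TRUE`).
#' @param coeff_init Initial value of all coefficients (default 0).
#' @return An `lms_config` list.
#' @export
lms_config <- function(n_harmonics = 5, mu = 0.02, normalized = TRUE,
                       coeff_init = 0) {
  if (n_harmonics < 1) stop("`n_harmonics` must be >= 1", call. = FALSE)
  if (mu < 0) stop("`mu` must be non-negative", call. = FALSE)
  structure(list(n_harmonics = n_harmonics, mu = mu,
                 normalized = normalized, coeff_init = coeff_init),
            class = "lms_config")
}

#' Per-sample instantaneous compression frequency
#'
#' Each compression cycle's instantaneous rate is the inverse of its cycle
#' length; every sample inside a cycle takes that cycle's value. Samples
#' before the first onset use the first cycle's value, samples after the
#' last onset the last cycle's.
#'
#' @param ref A [compression_reference] with at least 2 onsets.
#' @param n_samples Length of the track to produce.
#' @param fs Sampling rate of the track (Hz).
#' @return Numeric vector of `n_samples` frequencies in Hz.
#' @export
instantaneous_frequency <- function(ref, n_samples, fs) {
  if (!inherits(ref, "compression_reference")) {
    stop("`ref` must be a compression_reference", call. = FALSE)
  }
  on <- ref$onset_times
  cyc <- diff(on)
  t <- (seq_len(n_samples) - 1) / fs
  idx <- findInterval(t, on)
  idx[idx < 1] <- 1
  idx[idx > length(cyc)] <- length(cyc)
  1 / cyc[idx]
}

#' Harmonic LMS artifact cancellation
#'
#' Runs the compression-frequency-tracked harmonic canceller once, causally,
#' over a corrupted segment: at each sample the current harmonic model value
#' is subtracted to give the residual (the estimated VF signal), and the
#' coefficients are updated proportionally to the residual and the basis
#' values. Phase is accumulated (`phi(i) = phi(i-1) + f0(i)/fs`) so
#' frequency steps at cycle boundaries cause no phase jumps.
#'
#' @param corrupted Corrupted [ecg_segment] (role `CVF`/`SVF`).
#' @param f0 Per-sample compression-frequency track (Hz), same length as
#'   the segment; see [instantaneous_frequency()].
#' @param cfg An [lms_config()].
#' @return A list with `estimated_vf` and `artifact_estimate`
#'   ([ecg_segment]s) and the final coefficient vectors `a`, `b`.
#' @export
lms_cancel <- function(corrupted, f0, cfg = lms_config()) {
  stopifnot(is_ecg_segment(corrupted))
  x <- corrupted$samples
  n <- length(x)
  if (length(f0) != n) {
    stop("`f0` must have one value per sample of `corrupted`", call. = FALSE)
  }
  K <- cfg$n_harmonics
  fs <- corrupted$fs
  if (K * max(f0) >= fs / 2) {
    stop(sprintf("aliasing: %d harmonics at max f0 %.2f Hz reach Nyquist",
                 K, max(f0)), call. = FALSE)
  }
  phi <- cumsum(f0) / fs
  ks <- seq_len(K)
  # 2*pi*k*phi(i) for all k, i: K x n
  ang <- outer(2 * pi * ks, phi)
  Cb <- cos(ang)
  Sb <- sin(ang)
  a <- rep(cfg$coeff_init, K)
  b <- rep(cfg$coeff_init, K)
  e <- numeric(n)
  yhat <- numeric(n)
  step0 <- if (cfg$normalized) 2 * cfg$mu / K else 2 * cfg$mu
  for (i in seq_len(n)) {
    ci <- Cb[, i]
    si <- Sb[, i]
    y <- sum(a * ci) + sum(b * si)
    ei <- x[i] - y
    yhat[i] <- y
    e[i] <- ei
    st <- step0 * ei
    a <- a + st * ci
    b <- b + st * si
  }
  mk <- function(v, role) {
    ecg_segment(v, fs = fs, role = role, subject_id = corrupted$subject_id,
                t0 = corrupted$t0)
  }
  list(estimated_vf = mk(e, "UNKNOWN"),
       artifact_estimate = mk(yhat, "CC"),
       a = a, b = b)
}

#' AMSA after adaptive artifact cancellation
#'
#' The reference baseline estimator: cancel the compression artifact with
#' [lms_cancel()] using the frequency track derived from the compression
#' reference, then compute [amsa_fft()] on the residual.
#'
#' @param corrupted Corrupted [ecg_segment].
#' @param ref A [compression_reference] spanning the segment.
#' @param lms_cfg An [lms_config()].
#' @param spectral_cfg A [spectral_config()].
#' @return AMSA of the estimated VF signal, in mV Hz.
#' @export
amsa_adf <- function(corrupted, ref, lms_cfg = lms_config(),
                     spectral_cfg = spectral_config()) {
  f0 <- instantaneous_frequency(ref, length(corrupted$samples),
                                corrupted$fs)
  res <- lms_cancel(corrupted, f0, lms_cfg)
  amsa_fft(res$estimated_vf, spectral_cfg)
}
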