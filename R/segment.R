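#' ECG segment
#'
#' A fixed-rate single-lead waveform in millivolts with a role tag and
#' minimal acquisition metadata. Roles follow the segment taxonomy used
#' throughout the package: `UVF` (uncorrupted VF), `AVF` (adjacent
#' uncorrupted VF), `CVF` (compression-corrupted VF), `CC` (pure
#' compression artifact over asystole), `SVF` (simulated corrupted VF with
#' known truth), `PVF` (preshock VF) and `UNKNOWN`.
#'
#' @param samples Numeric vector of samples in mV; all values must be finite.
#' @param fs Sampling rate in Hz (default 250).
#' @param role Segment role, one of [segment_roles()].
#' @param subject_id Opaque subject identifier (default `NA`).
#' @param t0 Start time of the segment in seconds (default 0).
#'
#' @return An object of class `ecg_segment`.
#' @examples
#' s <- ecg_segment(sin(2 * pi * 5 * seq(0, 4, by = 1 / 250)[-1]), fs = 250)
#' duration(s)
#' @export
ecg_segment <- function(samples, fs = 250, role = "UNKNOWN",
                        subject_id = NA_character_, t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("`samples` must be non-empty", call. = FALSE)
  if (!all(is.finite(samples))) {
    stop("`samples` must be finite (found NA/NaN/Inf)", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  role <- match.arg(role, segment_roles())
  structure(
    list(samples = samples, fs = fs, role = role,
         subject_id = as.character(subject_id), t0 = as.numeric(t0)),
    class = "ecg_segment"
  )
}

#' @rdname ecg_segment
#' @export
segment_roles <- function() {
  c("UNKNOWN", "UVF", "AVF", "CVF", "CC", "SVF", "PVF")
}

#' @rdname ecg_segment
#' @param x,object An `ecg_segment`.
#' @export
is_ecg_segment <- function(x) inherits(x, "ecg_segment")

#' Segment duration in seconds
#' @param x An `ecg_segment`.
#' @return Duration in seconds (`length(samples) / fs`).
#' @export
duration <- function(x) {
  stopifnot(is_ecg_segment(x))
  length(x$samples) / x$fs
}

#' @export
print.ecg_segment <- function(x, ...) {
  cat(sprintf("<ecg_segment> role=%s fs=%g Hz n=%d (%.3f s) subject=%s\n",
              x$role, x$fs, length(x$samples), duration(x),
              x$subject_id))
  invisible(x)
}

#' @export
length.ecg_segment <- function(x) length(x$samples)

#' @rdname ecg_segment
#' @param ... Unused.
#' @export
as_tibble.ecg_segment <- function(x, ...) {
  tibble::tibble(
    t = x$t0 + (seq_along(x$samples) - 1) / x$fs,
    ecg_mv = x$samples
  )
}

#' Compression reference track
#'
#' Per-compression cycle boundaries recorded alongside the ECG (e.g. from a
#' compression-depth channel). Onset times must be strictly increasing and
#' consecutive cycle lengths must lie in \[0.3, 1.2\] s, i.e. 50-200
#' compressions/min.
#'
#' @param onset_times Strictly increasing compression onset times in seconds.
#' @param fs Sampling rate (Hz) of any per-sample track derived from the
#'   reference (default 250).
#' @return An object of class `compression_reference`.
#' @export
compression_reference <- function(onset_times, fs = 250) {
  onset_times <- as.numeric(onset_times)
  if (length(onset_times) < 2) {
    stop("a compression reference needs at least 2 onsets", call. = FALSE)
  }
  d <- diff(onset_times)
  if (any(d <= 0)) stop("onset times must be strictly increasing", call. = FALSE)
  if (any(d < 0.3 - 1e-9 | d > 1.2 + 1e-9)) {
    stop("compression cycle lengths must lie in [0.3, 1.2] s ",
         "(50-200 compressions/min)", call. = FALSE)
  }
  structure(list(onset_times = onset_times, fs = fs),
            class = "compression_reference")
}

#' @export
print.compression_reference <- function(x, ...) {
  cat(sprintf("<compression_reference> %d onsets over [%.2f, %.2f] s, mean rate %.1f/min\n",
              length(x$onset_times), min(x$onset_times), max(x$onset_times),
              60 / mean(diff(x$onset_times))))
  invisible(x)
}

#' Waveform plot for an ECG segment
#'
#' @param object An `ecg_segment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecg_segment <- function(object, ...) {
  df <- as_tibble.ecg_segment(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$ecg_mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "ECG (mV)",
                  title = sprintf("%s segment, fs = %g Hz", object$role,
                                  object$fs)) +
    ggplot2::theme_minimal()
}
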