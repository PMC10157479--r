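#' Resample a segment to a new rate
#'
#' Zero-phase windowed-sinc (Kaiser, beta 8) resampling with an
#' anti-aliasing cutoff at 90 percent of the lower Nyquist rate, so band
#' content below half the lower of the two rates is preserved without
#' group delay. Edges are reflection-padded. Device recordings arrive at
#' 125 or 250 Hz; all analysis in this package runs at 250 Hz, so ingest
#' normally ends with `resample_to(x, 250)`.
#'
#' @param segment An [ecg_segment].
#' @param target_fs Target sampling rate in Hz (> 0).
#' @return An [ecg_segment] at `target_fs` whose length is rescaled by
#'   `target_fs / fs`.
#' @export
resample_to <- function(segment, target_fs) {
  stopifnot(is_ecg_segment(segment))
  if (!is.numeric(target_fs) || length(target_fs) != 1 || target_fs <= 0) {
    stop("`target_fs` must be a single positive rate in Hz", call. = FALSE)
  }
  if (isTRUE(all.equal(target_fs, segment$fs))) return(segment)
  y <- sinc_resample(segment$samples, segment$fs, target_fs)
  ecg_segment(y, fs = target_fs, role = segment$role,
              subject_id = segment$subject_id, t0 = segment$t0)
}

sinc_resample <- function(x, fs_in, fs_out, half_width = 12, beta = 8) {
  r <- fs_out / fs_in
  n <- length(x)
  n_out <- round(n * r)
  A <- as.integer(ceiling(half_width / min(1, r)))
  fc <- 0.45 * min(1, r) # cycles per input sample
  xp <- c(rev(x[2:(A + 1)]), x, rev(x[(n - A):(n - 1)]))
  t0 <- (seq_len(n_out) - 1) / r
  base <- floor(t0)
  frac <- t0 - base
  j <- seq(-A + 1, A)
  u <- outer(-frac, j, "+")
  h <- ifelse(abs(u) < 1e-12, 2 * fc, sin(2 * pi * fc * u) / (pi * u))
  w <- besselI(beta * sqrt(pmax(0, 1 - (u / A)^2)), 0) / besselI(beta, 0)
  wt <- h * w
  wt <- wt / rowSums(wt) # unit DC gain on every polyphase branch
  idx <- outer(base + A + 1, j, "+")
  rowSums(matrix(xp[idx], nrow = n_out) * wt)
}

#' Extract adjacent corrupted/uncorrupted 4-s segment pairs
#'
#' Scans a continuous recording with a per-sample compression mask for the
#' two-window layout used to label training data: a 4-s window entirely free
#' of compressions adjacent (either order) to a 4-s window entirely covered
#' by compressions. The AMSA of the clean window, computed with
#' [amsa_fft()], is attached to the pair as the shared true label.
#'
#' @param ecg An [ecg_segment] (any duration >= 8 s for a non-empty result).
#' @param cc_mask Logical vector, one flag per sample, `TRUE` while
#'   compressions are ongoing.
#' @param window Window length in seconds (default 4).
#' @param slack Maximum tolerated gap, in samples, between the two windows
#'   (default 0: strict adjacency).
#' @param spectral_cfg A [spectral_config()] used for the label.
#' @return A tibble with one row per pair: list-columns `corrupted` and
#'   `uncorrupted` ([ecg_segment]s), `amsa_true` (mV Hz), `subject_id`,
#'   `t_clean`, `t_corrupt` (window start times, s).
#' @export
extract_segment_pairs <- function(ecg, cc_mask, window = 4, slack = 0,
                                  spectral_cfg = spectral_config()) {
  stopifnot(is_ecg_segment(ecg))
  cc_mask <- as.logical(cc_mask)
  n <- length(ecg$samples)
  if (length(cc_mask) != n) {
    stop("`cc_mask` must align sample-wise with `ecg`", call. = FALSE)
  }
  w <- round(window * ecg$fs)
  if (n < 2 * w) return(empty_pair_tibble())
  # classify every window start: clean (no CC) / covered (all CC)
  csum <- cumsum(c(0, cc_mask))
  starts <- seq_len(n - w + 1)
  inwin <- csum[starts + w] - csum[starts]
  clean <- inwin == 0
  covered <- inwin == w
  out <- list()
  for (s1 in starts) {
    for (gap in 0:slack) {
      s2 <- s1 + w + gap
      if (s2 > n - w + 1) break
      pair <- NULL
      if (clean[s1] && covered[s2]) pair <- c(clean = s1, corrupt = s2)
      if (covered[s1] && clean[s2]) pair <- c(clean = s2, corrupt = s1)
      if (!is.null(pair)) {
        out[[length(out) + 1]] <- pair
        break
      }
    }
  }
  if (length(out) == 0) return(empty_pair_tibble())
  rows <- purrr::map(out, function(p) {
    take <- function(s, role) {
      ecg_segment(ecg$samples[s:(s + w - 1)], fs = ecg$fs, role = role,
                  subject_id = ecg$subject_id, t0 = ecg$t0 + (s - 1) / ecg$fs)
    }
    clean_seg <- take(p[["clean"]], "UVF")
    corrupt_seg <- take(p[["corrupt"]], "CVF")
    tibble::tibble(
      corrupted = list(corrupt_seg), uncorrupted = list(clean_seg),
      amsa_true = amsa_fft(clean_seg, spectral_cfg),
      subject_id = ecg$subject_id,
      t_clean = clean_seg$t0, t_corrupt = corrupt_seg$t0
    )
  })
  dplyr::bind_rows(rows)
}

empty_pair_tibble <- function() {
  tibble::tibble(corrupted = list(), uncorrupted = list(),
                 amsa_true = numeric(0), subject_id = character(0),
                 t_clean = numeric(0), t_corrupt = numeric(0))
}
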