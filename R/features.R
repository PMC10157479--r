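#' Two-channel difference transform
#'
#' Builds the network input from a segment: after optional baseline removal
#' with [highpass()], the signal is downsampled by interleaved differencing
#' into two channels (1-based indexing over the filtered signal `S` of
#' length `L`):
#' `ch1(i) = S(2i+1) - S(2i-1)` and `ch2(i) = S(2i+2) - S(2i)` for
#' `i = 1 .. floor(L/2) - 1`, so a 1000-sample segment yields two channels
#' of length 499. Differencing removes the DC offset exactly and whitens
#' the low-frequency content, emphasising the frequency changes the
#' regressor feeds on.
#'
#' @param segment An [ecg_segment] with at least 4 samples.
#' @param hp Apply the 0.5 Hz high-pass first (default `TRUE`).
#' @param cfg A [spectral_config()] supplying the high-pass cutoff.
#' @return A `two_channel_input`: list with numeric `ch1`, `ch2` of equal
#'   length and the source metadata.
#' @export
difference_transform <- function(segment, hp = TRUE,
                                 cfg = spectral_config()) {
  stopifnot(is_ecg_segment(segment))
  if (length(segment$samples) < 4) {
    stop("segment too short for the difference transform (need >= 4 samples)",
         call. = FALSE)
  }
  s <- if (hp) highpass(segment, cfg)$samples else segment$samples
  L <- length(s)
  m <- floor(L / 2) - 1
  i <- seq_len(m)
  two_channel_input(ch1 = s[2 * i + 1] - s[2 * i - 1],
                    ch2 = s[2 * i + 2] - s[2 * i])
}

#' @rdname difference_transform
#' @param ch1,ch2 Equal-length numeric channels.
#' @export
two_channel_input <- function(ch1, ch2) {
  if (length(ch1) != length(ch2)) {
    stop("channels must have equal length", call. = FALSE)
  }
  if (!all(is.finite(ch1)) || !all(is.finite(ch2))) {
    stop("channels must be finite", call. = FALSE)
  }
  structure(list(ch1 = as.numeric(ch1), ch2 = as.numeric(ch2)),
            class = "two_channel_input")
}

#' @export
print.two_channel_input <- function(x, ...) {
  cat(sprintf("<two_channel_input> 2 x %d\n", length(x$ch1)))
  invisible(x)
}

#' @export
length.two_channel_input <- function(x) length(x$ch1)

#' The 7-variant augmentation group
#'
#' Returns the seven non-identity images of the input under the group
#' generated by three commuting involutions: negation of both channels,
#' time reversal of both channels, and channel swap. In order: negate;
#' reverse; swap; negate+reverse; negate+swap; reverse+swap;
#' negate+reverse+swap. Together with the identity these form a group of
#' order 8. Each operation preserves the per-channel magnitude spectrum
#' (up to the channel swap), so every variant legitimately carries the
#' source segment's AMSA label.
#'
#' @param x A `two_channel_input`.
#' @return List of 7 `two_channel_input` objects, in the order above.
#' @export
augment_variants <- function(x) {
  stopifnot(inherits(x, "two_channel_input"))
  neg <- function(z) two_channel_input(-z$ch1, -z$ch2)
  rev_ <- function(z) two_channel_input(rev(z$ch1), rev(z$ch2))
  swp <- function(z) two_channel_input(z$ch2, z$ch1)
  list(
    neg(x),
    rev_(x),
    swp(x),
    neg(rev_(x)),
    neg(swp(x)),
    rev_(swp(x)),
    neg(rev_(swp(x)))
  )
}
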