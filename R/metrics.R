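#' Estimation-accuracy metrics
#'
#' Computes the agreement bundle between estimated and true AMSA values:
#' mean absolute error `MAE = mean(|y - yhat|)`, root mean square error
#' `RMSE = sqrt(mean((y - yhat)^2))`, percentage root mean square
#' difference `PRD = 100 * sqrt(sum((y - yhat)^2) / sum(y^2))` and the
#' Spearman rank correlation (average ranks for ties).
#'
#' @param estimates Numeric vector of estimated values.
#' @param truths Numeric vector of true values, same length.
#' @return One-row tibble with `mae`, `rmse`, `prd`, `spearman_r`, `n`.
#' @examples
#' compute_metrics(c(2, 2, 2), c(1, 2, 3))
#' @export
compute_metrics <- function(estimates, truths) {
  if (length(estimates) != length(truths) || length(truths) == 0) {
    stop("`estimates` and `truths` must have equal non-zero length",
         call. = FALSE)
  }
  if (all(truths == 0)) {
    stop("PRD undefined: all true values are zero", call. = FALSE)
  }
  d <- estimates - truths
  sp <- if (length(truths) >= 2 && stats::sd(estimates) > 0 &&
            stats::sd(truths) > 0) {
    stats::cor(estimates, truths, method = "spearman")
  } else NA_real_
  tibble::tibble(
    mae = mean(abs(d)),
    rmse = sqrt(mean(d^2)),
    prd = 100 * sqrt(sum(d^2) / sum(truths^2)),
    spearman_r = sp,
    n = length(truths)
  )
}

#' Bland-Altman agreement
#'
#' Differences are taken as `estimate - truth`; the bias is their mean and
#' the limits of agreement are `bias +/- 1.96 * SD` (sample SD, n - 1
#' denominator).
#'
#' @param estimates,truths Numeric vectors of length >= 3.
#' @return A `bland_altman` object: tibble with `bias`, `loa_low`,
#'   `loa_high`, `sd_diff`, `n`, carrying the per-point means/differences
#'   as an attribute for plotting.
#' @export
bland_altman <- function(estimates, truths) {
  if (length(estimates) != length(truths) || length(truths) < 3) {
    stop("Bland-Altman needs at least 3 paired values", call. = FALSE)
  }
  d <- estimates - truths
  s <- stats::sd(d)
  out <- tibble::tibble(
    bias = mean(d),
    loa_low = mean(d) - 1.96 * s,
    loa_high = mean(d) + 1.96 * s,
    sd_diff = s,
    n = length(d)
  )
  attr(out, "points") <- tibble::tibble(mean = (estimates + truths) / 2,
                                        diff = d)
  class(out) <- c("bland_altman", class(out))
  out
}

#' Mean-difference plot of a Bland-Altman analysis
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  pts <- attr(object, "points")
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "mean of estimate and truth (mV Hz)",
                  y = "estimate - truth (mV Hz)") +
    ggplot2::theme_minimal()
}
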