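#' ROC curve and AUC for shock-success prediction
#'
#' The AUC is computed through the Mann-Whitney U identity (rank statistic
#' with half-credit for ties) and its standard error with the Hanley-McNeil
#' formula. The ROC curve itself is traced over all distinct score
#' thresholds.
#'
#' @param scores Numeric predictor (e.g. AMSA in mV Hz).
#' @param labels Binary outcomes (0/1 or logical); both classes must be
#'   present.
#' @return A `roc_result`: list with `auc`, `se`, `n_pos`, `n_neg` and a
#'   `curve` tibble (`threshold`, `tpr`, `fpr`).
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have equal length", call. = FALSE)
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  se <- hanley_mcneil_se(auc, n_pos, n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(scores[labels == 1] >= t), 0),
    fpr = vapply(thr, function(t) mean(scores[labels == 0] >= t), 0)
  )
  structure(list(auc = auc, se = se, n_pos = n_pos, n_neg = n_neg,
                 scores = scores, labels = labels, curve = curve),
            class = "roc_result")
}

# Hanley & McNeil (1982) standard error of an AUC
hanley_mcneil_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (SE %.3f), %d positive / %d negative\n",
              x$auc, x$se, x$n_pos, x$n_neg))
  invisible(x)
}

#' Compare two correlated AUCs
#'
#' Both ROC results must be computed on the same cases (paired design).
#' The default method is DeLong's nonparametric test on the placement
#' values; `"hanley_mcneil"` applies the Hanley-McNeil (1983) z-test with
#' their tabulated-correlation approximation, estimating the score
#' correlation from the data.
#'
#' @param r1,r2 `roc_result` objects from [roc_auc()] on the same cases.
#' @param method `"delong"` (default) or `"hanley_mcneil"`.
#' @return One-row tibble with `auc1`, `auc2`, `z`, `p_value`, `method`.
#' @export
compare_auc <- function(r1, r2, method = c("delong", "hanley_mcneil")) {
  method <- match.arg(method)
  stopifnot(inherits(r1, "roc_result"), inherits(r2, "roc_result"))
  if (length(r1$labels) != length(r2$labels) ||
      any(r1$labels != r2$labels)) {
    stop("paired comparison requires identical cases and labels",
         call. = FALSE)
  }
  if (method == "delong") {
    v1 <- placement_values(r1$scores, r1$labels)
    v2 <- placement_values(r2$scores, r2$labels)
    d10 <- cbind(v1$v10, v2$v10)
    d01 <- cbind(v1$v01, v2$v01)
    s10 <- stats::cov(d10)
    s01 <- stats::cov(d01)
    S <- s10 / r1$n_pos + s01 / r1$n_neg
    var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
    z <- if (var_diff <= 0) 0 else (r1$auc - r2$auc) / sqrt(var_diff)
  } else {
    rp <- stats::cor(r1$scores[r1$labels == 1], r2$scores[r2$labels == 1])
    rn <- stats::cor(r1$scores[r1$labels == 0], r2$scores[r2$labels == 0])
    r_avg <- (rp + rn) / 2
    if (!is.finite(r_avg)) r_avg <- 0
    # Hanley-McNeil 1983 approximate correlation of the two AUC estimates
    r_auc <- r_avg * (1 - (r1$auc - r2$auc)^2 / 2)
    var_diff <- r1$se^2 + r2$se^2 - 2 * r_auc * r1$se * r2$se
    z <- if (var_diff <= 0) 0 else (r1$auc - r2$auc) / sqrt(var_diff)
  }
  tibble::tibble(auc1 = r1$auc, auc2 = r2$auc, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)), method = method)
}

# DeLong placement values: v10 per positive, v01 per negative
placement_values <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), 0)
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), 0)
  list(v10 = v10, v01 = v01)
}

#' ROC curve plot
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, se = x$se, n_pos = x$n_pos, n_neg = x$n_neg)
}
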