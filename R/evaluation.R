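#' Confusion counts
#'
#' Exact two-class confusion counts with a declared positive class.
#'
#' @param truth true labels.
#' @param estimate predicted labels, same length.
#' @param positive the class counted as positive.
#' @return A one-row tibble with `tp`, `fp`, `fn`, `tn`, `n`, `positive`.
#' @export
confusion_counts <- function(truth, estimate, positive) {
  if (length(truth) != length(estimate) || length(truth) < 1L) {
    abort("`truth` and `estimate` must have equal length >= 1.",
          class = "roughpnn_error_value")
  }
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  if (!positive %in% c(truth, estimate)) {
    abort(paste0("Positive class '", positive, "' not present in the labels."),
          class = "roughpnn_error_value")
  }
  tibble::tibble(
    tp = sum(truth == positive & estimate == positive),
    fp = sum(truth != positive & estimate == positive),
    fn = sum(truth == positive & estimate != positive),
    tn = sum(truth != positive & estimate != positive),
    n = length(truth),
    positive = positive
  )
}

#' Accuracy, precision and recall from confusion counts
#'
#' Ratios with an empty denominator (e.g. precision when nothing was
#' predicted positive) are reported as `NA`, not 0.
#'
#' @param counts a one-row tibble from [confusion_counts()].
#' @return A one-row tibble with `accuracy`, `precision`, `recall`.
#' @export
classification_metrics <- function(counts) {
  tibble::tibble(
    accuracy = (counts$tp + counts$tn) / counts$n,
    precision = ifelse(counts$tp + counts$fp > 0,
                       counts$tp / (counts$tp + counts$fp), NA_real_),
    recall = ifelse(counts$tp + counts$fn > 0,
                    counts$tp / (counts$tp + counts$fn), NA_real_)
  )
}

#' Wilson score interval for a proportion
#'
#' The two-sided Wilson score interval for `successes / n`, clipped to
#' `[0, 1]`.
#'
#' @param successes number of successes, `0 <= successes <= n`.
#' @param n number of trials, `n >= 1`.
#' @param level confidence level in `(0, 1)`; default 0.95.
#' @return A one-row tibble with `low`, `high`.
#' @export
proportion_ci <- function(successes, n, level = 0.95) {
  if (n < 1 || successes < 0 || successes > n || level <= 0 || level >= 1) {
    abort("Need 0 <= successes <= n, n >= 1 and 0 < level < 1.",
          class = "roughpnn_error_value")
  }
  z <- qnorm(1 - (1 - level) / 2)
  phat <- successes / n
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2))
  tibble::tibble(
    low = max(0, center - half),
    high = min(1, center + half)
  )
}

#' Full confusion report
#'
#' Bundles confusion counts, the derived metrics and a Wilson interval for
#' the accuracy into one object. `elapsed_seconds` is carried for logging
#' only and never enters any comparison.
#'
#' @inheritParams confusion_counts
#' @param level confidence level for the accuracy interval.
#' @param elapsed_seconds optional wall-clock seconds to record.
#' @return A one-row tibble of class `confusion_report`.
#' @export
confusion_report <- function(truth, estimate, positive, level = 0.95,
                             elapsed_seconds = NA_real_) {
  counts <- confusion_counts(truth, estimate, positive)
  mets <- classification_metrics(counts)
  ci <- proportion_ci(counts$tp + counts$tn, counts$n, level)
  out <- dplyr::bind_cols(counts, mets,
                          tibble::tibble(ci_low = ci$low, ci_high = ci$high,
                                         ci_level = level,
                                         elapsed_seconds = elapsed_seconds))
  class(out) <- c("confusion_report", class(out))
  out
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf("<confusion_report> positive = %s, n = %d\n", x$positive, x$n))
  cat(sprintf("  tp = %d  fp = %d  fn = %d  tn = %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  accuracy = %.4f  [%.4f, %.4f] (%.0f%% Wilson)\n",
              x$accuracy, x$ci_low, x$ci_high, 100 * x$ci_level))
  cat(sprintf("  precision = %s  recall = %s\n",
              format_prop(x$precision), format_prop(x$recall)))
  invisible(x)
}

format_prop <- function(p) {
  if (is.na(p)) "undefined" else sprintf("%.4f", p)
}
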