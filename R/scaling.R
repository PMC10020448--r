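#' Per-attribute scaling statistics
#'
#' Fits scaling statistics on a decision table. Two variants are supported,
#' each used where its units make the pipeline defaults meaningful:
#'
#' * `"minmax"` (default) records per-attribute minimum and maximum; applying
#'   maps every fitted attribute into `[0, 1]`. Used for neighborhood
#'   granulation, whose default radius (0.15) is in min-max units.
#' * `"zscore"` records per-attribute mean and standard deviation; applying
#'   centers and scales to unit SD. Used for the PNN inputs, whose default
#'   kernel spread (0.75) is in SD units.
#'
#' Scaling is always fitted on the training portion only and applied to both
#' portions: the neighborhood radius and the Gaussian kernel are
#' scale-sensitive, so a common fitted scale keeps defaults meaningful and
#' avoids test-set leakage.
#'
#' @param data a decision table.
#' @param method `"minmax"` or `"zscore"`.
#' @return A tibble of class `scaling_stats` with columns `attribute`,
#'   `center`, `scale`, plus `min`/`max` for the min-max variant, and a
#'   `method` attribute.
#' @export
fit_scaling <- function(data, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  validate_decision_table(data)
  x <- feature_matrix(data)
  if (method == "minmax") {
    lo <- apply(x, 2, min)
    hi <- apply(x, 2, max)
    out <- tibble::tibble(attribute = seq_len(ncol(x)),
                          center = lo, scale = hi - lo, min = lo, max = hi)
  } else {
    out <- tibble::tibble(attribute = seq_len(ncol(x)),
                          center = colMeans(x),
                          scale = apply(x, 2, stats::sd))
  }
  attr(out, "method") <- method
  class(out) <- c("scaling_stats", class(out))
  out
}

#' Apply (or invert) fitted scaling
#'
#' Maps each attribute through `(x - center) / scale` with the fitted
#' statistics; constant attributes (`scale == 0`) map to 0. Min-max scaled
#' values land in `[0, 1]` on the fitting table; unseen data extrapolates
#' linearly.
#'
#' @param stats a `scaling_stats` object from [fit_scaling()].
#' @param data a decision table with the same attribute count.
#' @param invert if `TRUE`, undo the scaling instead.
#' @return The rescaled decision table.
#' @export
apply_scaling <- function(stats, data, invert = FALSE) {
  validate_decision_table(data)
  acols <- attribute_names(data)
  if (length(acols) != nrow(stats)) {
    abort(sprintf(
      "Scaling stats cover %d attributes but the table has %d.",
      nrow(stats), length(acols)),
      class = "roughpnn_error_shape")
  }
  x <- as.matrix(data[acols])
  for (j in seq_along(acols)) {
    if (stats$scale[j] <= 0) {
      x[, j] <- if (invert) stats$center[j] else 0
    } else if (invert) {
      x[, j] <- x[, j] * stats$scale[j] + stats$center[j]
    } else {
      x[, j] <- (x[, j] - stats$center[j]) / stats$scale[j]
    }
  }
  data[acols] <- x
  data
}
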