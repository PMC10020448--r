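#' Tidy an attribute reduct
#'
#' Returns the accepted search trace, one row per step, with non-increasing
#' risks along the accepted path.
#'
#' @param x an `spdtrs_reduct`.
#' @param ... unused.
#' @return A tibble with `step`, `action`, `attribute`, `risk`.
#' @export
tidy.spdtrs_reduct <- function(x, ...) {
  tr <- x$trace
  dplyr::mutate(tibble::as_tibble(tr[intersect(c("action", "attribute", "risk"),
                                               names(tr))]),
                step = dplyr::row_number(), .before = 1)
}

#' @rdname tidy.spdtrs_reduct
#' @export
glance.spdtrs_reduct <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$selected),
    risk_B = x$risk,
    risk_C = x$risk_C,
    xi = x$xi,
    delta = x$delta,
    no_reduct = x$no_reduct,
    method = x$method
  )
}

#' Tidy a fitted PNN
#'
#' @param x a `pnn` model.
#' @param ... unused.
#' @return One row per class with its training count and prior.
#' @export
tidy.pnn <- function(x, ...) {
  tibble::tibble(
    class = factor(x$levels, levels = x$levels),
    count = x$counts,
    prior = x$priors
  )
}

#' @rdname tidy.pnn
#' @export
glance.pnn <- function(x, ...) {
  tibble::tibble(n = x$n, b = x$b, sigma = x$sigma,
                 n_classes = length(x$levels))
}

#' Tidy a confusion report
#'
#' @param x a `confusion_report`.
#' @param ... unused.
#' @return Long tibble of the four confusion cells.
#' @export
tidy.confusion_report <- function(x, ...) {
  tibble::tibble(
    cell = c("tp", "fp", "fn", "tn"),
    count = c(x$tp, x$fp, x$fn, x$tn)
  )
}

#' @rdname tidy.confusion_report
#' @export
glance.confusion_report <- function(x, ...) {
  tibble::as_tibble(x[c("n", "accuracy", "precision", "recall",
                        "ci_low", "ci_high", "ci_level")])
}

#' Plot the reduct search trace
#'
#' Risk against accepted search step; the curve is non-increasing along
#' accepted additions/drops.
#'
#' @param object an `spdtrs_reduct`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.spdtrs_reduct <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$action %in% c("add", "drop", "refine"), , drop = FALSE]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$step, y = .data$risk)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$action)) +
    ggplot2::geom_hline(yintercept = object$risk_C, linetype = "dashed") +
    ggplot2::labs(x = "accepted search step", y = "overall Bayes risk",
                  title = sprintf("Reduct search (xi = %g, delta = %g)",
                                  object$xi, object$delta),
                  caption = "dashed line: full attribute set")
}

#' Plot a parameter sweep
#'
#' Train and test accuracy against the swept parameter (compensation
#' coefficient or kernel spread).
#'
#' @param object an `xi_sweep` or `spread_sweep`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.xi_sweep <- function(object, ...) {
  sweep_plot(object, "xi", "compensation coefficient xi")
}

#' @rdname autoplot.xi_sweep
#' @export
autoplot.spread_sweep <- function(object, ...) {
  sweep_plot(object, "sigma", "kernel spread sigma")
}

sweep_plot <- function(object, par_col, par_lab) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c(par_col, "train_acc", "test_acc")],
    cols = c("train_acc", "test_acc"),
    names_to = "set", values_to = "accuracy")
  long$set <- ifelse(long$set == "train_acc", "train", "test")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[par_col]], y = .data$accuracy,
                                     color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = par_lab, y = "accuracy", color = NULL)
}

#' Plot a confusion report
#'
#' 2x2 tile plot of the confusion counts.
#'
#' @param object a `confusion_report`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.confusion_report <- function(object, ...) {
  df <- tibble::tibble(
    truth = c("positive", "negative", "positive", "negative"),
    predicted = c("positive", "positive", "negative", "negative"),
    count = c(object$tp, object$fp, object$fn, object$tn)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::labs(title = sprintf("Confusion (positive = %s)", object$positive))
}
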