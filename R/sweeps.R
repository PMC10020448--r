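#' Restrict a decision table to an attribute subset
#'
#' Keeps only the requested attributes, renumbering the columns `a1..am` in
#' the order given (the classifier does not care about original labels; keep
#' the returned mapping if you do).
#'
#' @param data a decision table.
#' @param subset integer attribute labels.
#' @return A decision table with `length(subset)` attributes.
#' @export
select_attributes <- function(data, subset) {
  x <- feature_matrix(data, subset)
  decision_table(x, data$label, ids = data$id)
}

#' Compensation-coefficient sweep
#'
#' Runs the full reduce-then-classify pipeline once per value of the
#' compensation coefficient `xi`, holding the split, the scaling and the
#' kernel spread fixed. The default grid is 0.05 to 0.40 in steps of 0.05
#' (eight runs), covering the whole recommended range of `xi`.
#'
#' For each grid value: scaling is fitted on the training portion (min-max
#' for granulation, z-score for the classifier), the reduct is computed on
#' the scaled training table, a PNN with spread `sigma` is fitted on the
#' selected attributes, and train/test accuracies are recorded. Elapsed wall-clock seconds are logged but carry no
#' significance.
#'
#' @param data a decision table.
#' @param xi_grid numeric grid of compensation coefficients.
#' @param delta neighborhood radius (scaled units).
#' @param sigma PNN spread.
#' @param train_counts named class -> count vector for the stratified split.
#' @param seed split seed (the split is identical across the grid).
#' @param positive positive class for the confusion metrics; defaults to the
#'   first label level.
#' @return A tibble of class `xi_sweep`: one row per `xi` with `xi`, `dim`,
#'   `selected` (list-column), `train_acc`, `test_acc`, `elapsed_s`.
#' @export
sweep_xi <- function(data, xi_grid = seq(0.05, 0.40, by = 0.05),
                     delta = 0.15, sigma = 0.75, train_counts, seed = 1L,
                     positive = levels(data$label)[1]) {
  if (length(xi_grid) < 1L) {
    abort("`xi_grid` must be non-empty.", class = "roughpnn_error_value")
  }
  split <- stratified_split(data, train_counts, seed = seed)
  scaling_g <- fit_scaling(split$train, method = "minmax")
  train_g <- apply_scaling(scaling_g, split$train)
  scaling_p <- fit_scaling(split$train, method = "zscore")
  train_p <- apply_scaling(scaling_p, split$train)
  test_p <- apply_scaling(scaling_p, split$test)
  rows <- lapply(xi_grid, function(xi) {
    t0 <- proc.time()[["elapsed"]]
    red <- reduce_attributes(train_g, xi = xi, delta = delta)
    model <- pnn(select_attributes(train_p, red$selected), sigma = sigma)
    train_acc <- mean(predict(model, select_attributes(train_p, red$selected)) ==
                        train_p$label)
    test_acc <- mean(predict(model, select_attributes(test_p, red$selected)) ==
                       test_p$label)
    tibble::tibble(
      xi = xi,
      dim = length(red$selected),
      selected = list(red$selected),
      train_acc = train_acc,
      test_acc = test_acc,
      elapsed_s = proc.time()[["elapsed"]] - t0
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("xi_sweep", class(out))
  out
}

#' Kernel-spread sweep
#'
#' Fits a PNN at every spread value on a fixed train table and records
#' train/test accuracy. The default grid is 0.50 to 1.55 in steps of 0.05
#' (22 runs), covering the recommended spread range with its upper fringe.
#'
#' @param train,test decision tables (test disjoint from train). Scaling is
#'   fitted on `train` and applied to both.
#' @param selected optional attribute subset to restrict both tables to
#'   before fitting (e.g. a reduct); default uses all attributes.
#' @param spread_grid numeric grid of spreads, all positive.
#' @return A tibble of class `spread_sweep`: one row per spread with
#'   `sigma`, `train_acc`, `test_acc`, `elapsed_s`.
#' @export
sweep_spread <- function(train, test, selected = NULL,
                         spread_grid = seq(0.50, 1.55, by = 0.05)) {
  if (length(spread_grid) < 1L || any(spread_grid <= 0)) {
    abort("`spread_grid` must be non-empty and positive.",
          class = "roughpnn_error_value")
  }
  if (!is.null(selected)) {
    train <- select_attributes(train, selected)
    test <- select_attributes(test, selected)
  }
  scaling <- fit_scaling(train, method = "zscore")
  train_s <- apply_scaling(scaling, train)
  test_s <- apply_scaling(scaling, test)
  rows <- lapply(spread_grid, function(sg) {
    t0 <- proc.time()[["elapsed"]]
    model <- pnn(train_s, sigma = sg)
    tibble::tibble(
      sigma = sg,
      train_acc = mean(predict(model, train_s) == train_s$label),
      test_acc = mean(predict(model, test_s) == test_s$label),
      elapsed_s = proc.time()[["elapsed"]] - t0
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("spread_sweep", class(out))
  out
}

#' Write sweep records as CSV
#'
#' Flattens a sweep tibble to the on-disk record format
#' `parameter,dim,train_acc,test_acc,elapsed_s`.
#'
#' @param sweep an `xi_sweep` or `spread_sweep`.
#' @param path output file.
#' @export
write_sweep_csv <- function(sweep, path) {
  if (inherits(sweep, "xi_sweep")) {
    flat <- tibble::tibble(
      parameter = sweep$xi,
      dim = sweep$dim,
      selected = vapply(sweep$selected, paste, character(1), collapse = " "),
      train_acc = sweep$train_acc,
      test_acc = sweep$test_acc,
      elapsed_s = sweep$elapsed_s
    )
  } else {
    flat <- tibble::tibble(
      parameter = sweep$sigma,
      dim = NA_integer_,
      selected = NA_character_,
      train_acc = sweep$train_acc,
      test_acc = sweep$test_acc,
      elapsed_s = sweep$elapsed_s
    )
  }
  utils::write.csv(flat, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
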