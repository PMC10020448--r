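#' Fit a probabilistic neural network
#'
#' A PNN is a lazy Parzen-kernel classifier: fitting stores the training
#' vectors grouped by class together with class counts `c_i`, priors
#' `p_i = c_i / n` and the Gaussian smoothing factor `sigma` (the SPREAD).
#' There is no iterative optimization. Prediction evaluates, for a query
#' `x`, the pattern-layer kernels
#' `psi_ij(x) = (2*pi)^(-b/2) * sigma^(-b) * exp(-||x - x_ij||^2 / (2*sigma^2))`,
#' averages them within each class (summation layer), weights by the priors
#' and returns the argmax class (output layer).
#'
#' @param data a decision table used as training set; every declared class
#'   must have at least one sample. Features are expected in scaled units
#'   (see `scaling`).
#' @param sigma positive smoothing factor in scaled-feature units; the
#'   default 0.75 is the operating point selected by the SPREAD sweep.
#' @param scaling optional [fit_scaling()] stats. When supplied, the training
#'   features are assumed already scaled and `predict()` applies the same
#'   scaling to new data automatically.
#' @return An object of class `pnn`.
#' @export
pnn <- function(data, sigma = 0.75, scaling = NULL) {
  validate_decision_table(data, require_all_classes = TRUE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    abort("`sigma` must be a single positive number.", class = "roughpnn_error_value")
  }
  x <- feature_matrix(data)
  cls <- factor(data$label)
  counts <- table(cls)
  structure(
    list(
      x = x,
      class = cls,
      levels = levels(cls),
      counts = as.integer(counts),
      priors = as.numeric(counts) / nrow(x),
      sigma = sigma,
      b = ncol(x),
      n = nrow(x),
      scaling = scaling
    ),
    class = "pnn"
  )
}

# log of the shared Gaussian normalizing constant (2 pi)^(-b/2) sigma^(-b)
log_kernel_const <- function(model) {
  -(model$b / 2) * log(2 * pi) - model$b * log(model$sigma)
}

# squared distances from each query row to each training row
query_sq_dist <- function(model, xq) {
  if (ncol(xq) != model$b) {
    abort(sprintf("Query dimension %d does not match model dimension %d.",
                  ncol(xq), model$b),
          class = "roughpnn_error_shape")
  }
  d2 <- outer(rowSums(xq^2), rowSums(model$x^2), "+") - 2 * tcrossprod(xq, model$x)
  d2[d2 < 0] <- 0
  d2
}

# coerce predict()/pattern_outputs() input to a scaled query matrix
query_matrix <- function(model, newdata) {
  if (is.data.frame(newdata)) {
    if (!is.null(model$scaling)) {
      newdata <- apply_scaling(model$scaling, newdata)
    }
    xq <- feature_matrix(newdata)
  } else {
    xq <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  }
  xq
}

#' Pattern-layer kernel outputs
#'
#' Evaluates the Gaussian kernel of every stored training vector at a single
#' query point. Values lie in `(0, (2*pi)^(-b/2) * sigma^(-b)]`, attaining
#' the maximum when the query coincides with a training vector. Very distant
#' pairs can underflow to zero in double precision; class scores and
#' predictions use log-domain accumulation instead and are immune.
#'
#' @param model a fitted [pnn()].
#' @param x one query: a numeric vector of length `b` (scaled units) or a
#'   one-row decision table.
#' @return A tibble with one row per training vector: `class`, `j` (index
#'   within its class), `psi`.
#' @export
pattern_outputs <- function(model, x) {
  xq <- query_matrix(model, x)
  if (nrow(xq) != 1L) {
    abort("`pattern_outputs()` takes a single query point.",
          class = "roughpnn_error_shape")
  }
  d2 <- query_sq_dist(model, xq)[1, ]
  psi <- exp(log_kernel_const(model) - d2 / (2 * model$sigma^2))
  ord <- order(as.integer(model$class))
  tibble::tibble(
    class = model$class[ord],
    j = unlist(lapply(model$counts, seq_len)),
    psi = psi[ord]
  )
}

# per-class log scores: log(p_i) + log(g_i), computed by log-sum-exp
log_class_scores <- function(model, xq) {
  e <- -query_sq_dist(model, xq) / (2 * model$sigma^2)
  lc <- log_kernel_const(model)
  out <- matrix(NA_real_, nrow(xq), length(model$levels),
                dimnames = list(NULL, model$levels))
  for (i in seq_along(model$levels)) {
    cols <- which(model$class == model$levels[i])
    ei <- e[, cols, drop = FALSE]
    m <- apply(ei, 1, max)
    lg <- m + log(rowSums(exp(ei - m))) - log(length(cols)) + lc
    out[, i] <- log(model$priors[i]) + lg
  }
  out
}

#' Summation-layer class scores
#'
#' For a single query, returns each class's summation-layer output
#' `g_i = mean(psi_ij)` and the prior-weighted output-layer operand
#' `p_i * g_i`. The scores obey the mixture identity
#' `sum_i p_i * g_i = (1/n) * sum_ij psi_ij`.
#'
#' @inheritParams pattern_outputs
#' @return A tibble with one row per class: `class`, `prior`, `g`, `score`.
#' @export
class_scores <- function(model, x) {
  xq <- query_matrix(model, x)
  if (nrow(xq) != 1L) {
    abort("`class_scores()` takes a single query point.",
          class = "roughpnn_error_shape")
  }
  ls <- log_class_scores(model, xq)[1, ]
  score <- unname(exp(ls))
  tibble::tibble(
    class = factor(model$levels, levels = model$levels),
    prior = model$priors,
    g = score / model$priors,
    score = score
  )
}

#' Predict with a fitted PNN
#'
#' Output layer: the predicted label is the class maximizing the
#' prior-weighted summation-layer output `p_i * g_i(x)`. Ties break to the
#' lowest class index (first factor level). Scores are accumulated in the
#' log domain, so predictions remain correct for tiny `sigma` where the raw
#' kernels underflow.
#'
#' @param object a fitted [pnn()].
#' @param newdata a decision table, or a numeric matrix of scaled query rows.
#' @param type `"class"` for labels, `"score"` for the matrix of per-class
#'   log scores.
#' @param ... unused.
#' @return A factor of predicted labels, or a log-score matrix.
#' @export
predict.pnn <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  xq <- query_matrix(object, newdata)
  ls <- log_class_scores(object, xq)
  if (type == "score") {
    return(ls)
  }
  idx <- apply(ls, 1, which.max)
  factor(object$levels[idx], levels = object$levels)
}

#' @export
print.pnn <- function(x, ...) {
  cat(sprintf("<pnn> %d training vectors, %d classes, b = %d, sigma = %g\n",
              x$n, length(x$levels), x$b, x$sigma))
  for (i in seq_along(x$levels)) {
    cat(sprintf("  %s: c = %d, prior = %.4f\n",
                x$levels[i], x$counts[i], x$priors[i]))
  }
  invisible(x)
}

#' Serialize / restore a PNN model as JSON
#'
#' Stores training vectors, class labels, counts, smoothing factor and the
#' scaling stats (if any) in a single JSON bundle.
#'
#' @param model a fitted [pnn()].
#' @param path file path.
#' @return `read_pnn_json()` returns the restored `pnn` object.
#' @export
write_pnn_json <- function(model, path) {
  obj <- list(
    levels = model$levels,
    class = as.character(model$class),
    x = model$x,
    sigma = model$sigma,
    scaling = if (!is.null(model$scaling)) {
      list(attribute = model$scaling$attribute,
           center = model$scaling$center, scale = model$scaling$scale,
           method = attr(model$scaling, "method") %||% "minmax")
    }
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_pnn_json
#' @export
read_pnn_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  x <- as.matrix(obj$x)
  colnames(x) <- paste0("a", seq_len(ncol(x)))
  scaling <- NULL
  if (!is.null(obj$scaling)) {
    scaling <- tibble::tibble(attribute = obj$scaling$attribute,
                              center = obj$scaling$center,
                              scale = obj$scaling$scale)
    attr(scaling, "method") <- obj$scaling$method
    class(scaling) <- c("scaling_stats", class(scaling))
  }
  tbl <- decision_table(x, factor(obj$class, levels = obj$levels))
  pnn(tbl, sigma = obj$sigma, scaling = scaling)
}
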