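#' Build a decision table
#'
#' A decision table is the package's central data structure: a tibble holding a
#' universe of samples described by real-valued condition attributes and one
#' nominal decision attribute. The layout is fixed: an `id` column (opaque
#' sample identifiers), a `label` factor (the decision classes, e.g. benign vs
#' malignant), and numeric attribute columns named `a1`, `a2`, ... `aK`.
#' Attribute *j* is always addressed by its 1-based index `j`, matching the
#' conventional 1-30 numbering of the Wisconsin diagnostic features (1-10
#' means, 11-20 standard errors, 21-30 worst values).
#'
#' @param features numeric matrix or data frame, `n_samples x n_attributes`,
#'   no missing values.
#' @param labels vector of decision labels, one per sample; coerced to factor.
#' @param ids optional sample identifiers; defaults to `"s1"`, `"s2"`, ...
#'
#' @return A tibble of class `decision_table` with columns `id`, `label`,
#'   `a1` ... `aK`.
#' @examples
#' decision_table(matrix(rnorm(20), 10, 2), rep(c("benign", "malignant"), 5))
#' @export
decision_table <- function(features, labels, ids = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features)) {
    abort("`features` must be numeric.", class = "roughpnn_error_value")
  }
  n <- nrow(features)
  k <- ncol(features)
  if (n < 1L || k < 1L) {
    abort("A decision table needs at least one sample and one attribute.",
          class = "roughpnn_error_value")
  }
  if (anyNA(features)) {
    abort("`features` must not contain missing values.",
          class = "roughpnn_error_value")
  }
  if (length(labels) != n) {
    abort("`labels` must have one entry per sample.",
          class = "roughpnn_error_value")
  }
  ids <- ids %||% paste0("s", seq_len(n))
  colnames(features) <- paste0("a", seq_len(k))
  out <- tibble::tibble(
    id = as.character(ids),
    label = if (is.factor(labels)) labels else factor(labels)
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(features))
  class(out) <- c("decision_table", class(out))
  out
}

#' Validate the decision-table contract
#'
#' Checks the invariants every fitting routine relies on: complete numeric
#' features, consistent attribute naming, and (optionally) at least one sample
#' in every declared class.
#'
#' @param data a decision table (tibble with `id`, `label`, `a*` columns).
#' @param require_all_classes if `TRUE`, error when a declared factor level has
#'   no samples (a table unusable for fitting).
#' @return `data`, invisibly, on success.
#' @export
validate_decision_table <- function(data, require_all_classes = FALSE) {
  if (!is.data.frame(data)) {
    abort("A decision table must be a data frame.", class = "roughpnn_error_value")
  }
  if (!all(c("id", "label") %in% names(data))) {
    abort("A decision table needs `id` and `label` columns.",
          class = "roughpnn_error_value")
  }
  acols <- attribute_names(data)
  if (length(acols) < 1L) {
    abort("A decision table needs at least one attribute column `a1`, `a2`, ...",
          class = "roughpnn_error_value")
  }
  expect <- paste0("a", seq_along(acols))
  if (!identical(acols, expect)) {
    abort("Attribute columns must be named a1..aK consecutively.",
          class = "roughpnn_error_value")
  }
  x <- as.matrix(data[acols])
  if (!is.numeric(x) || anyNA(x)) {
    abort("Attribute columns must be numeric with no missing values.",
          class = "roughpnn_error_value")
  }
  if (nrow(data) < 1L) {
    abort("A decision table needs at least one sample.",
          class = "roughpnn_error_value")
  }
  if (require_all_classes) {
    cnt <- table(data$label)
    if (any(cnt == 0L)) {
      abort(paste0("Every declared class needs at least one sample; empty: ",
                   paste(names(cnt)[cnt == 0L], collapse = ", ")),
            class = "roughpnn_error_value")
    }
  }
  invisible(data)
}

# Attribute column names in index order.
attribute_names <- function(data) {
  nm <- grep("^a[0-9]+$", names(data), value = TRUE)
  nm[order(as.integer(sub("^a", "", nm)))]
}

#' Number of condition attributes in a decision table
#' @param data a decision table.
#' @return integer count of `a*` columns.
#' @export
n_attributes <- function(data) length(attribute_names(data))

# Extract the feature matrix, optionally restricted to attribute subset B
# (integer labels). Unknown labels raise a key error.
feature_matrix <- function(data, subset = NULL) {
  acols <- attribute_names(data)
  if (is.null(subset)) {
    return(as.matrix(data[acols]))
  }
  subset <- as.integer(subset)
  if (length(subset) == 0L) {
    abort("Attribute subset must be non-empty.", class = "roughpnn_error_value")
  }
  want <- paste0("a", subset)
  missing <- setdiff(want, acols)
  if (length(missing) > 0L) {
    abort(paste0("Unknown attribute label(s): ",
                 paste(sub("^a", "", missing), collapse = ", ")),
          class = "roughpnn_error_key")
  }
  as.matrix(data[want])
}
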