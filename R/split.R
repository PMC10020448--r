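#' Stratified train/test split with exact class counts
#'
#' Splits a decision table into disjoint training and test tables by seeded
#' uniform sampling without replacement, drawing exactly the requested number
#' of training samples from each class; everything else goes to the test set.
#' The canonical operating point for the 569-sample diagnostic table is 250
#' benign + 150 malignant in training, leaving 107 benign + 62 malignant for
#' testing.
#'
#' @param data a decision table.
#' @param train_counts named numeric vector, class label -> training count.
#' @param seed integer seed; the same seed always yields the same split.
#' @return A list with elements `train` and `test` (decision tables).
#' @examples
#' tbl <- generate_table(synthetic_spec(n_per_class = c(benign = 20, malignant = 12),
#'                                      k_informative = 2, seed = 1))
#' sp <- stratified_split(tbl, c(benign = 12, malignant = 8), seed = 7)
#' nrow(sp$train); nrow(sp$test)
#' @export
stratified_split <- function(data, train_counts, seed = 1L) {
  validate_decision_table(data)
  if (is.null(names(train_counts)) || any(!nzchar(names(train_counts)))) {
    abort("`train_counts` must be a named vector of class counts.",
          class = "roughpnn_error_value")
  }
  avail <- table(data$label)
  for (cls in names(train_counts)) {
    if (!cls %in% names(avail)) {
      abort(paste0("Unknown class in `train_counts`: ", cls),
            class = "roughpnn_error_value")
    }
    if (train_counts[[cls]] > avail[[cls]]) {
      abort(sprintf("Requested %d training samples of class '%s' but only %d exist.",
                    train_counts[[cls]], cls, avail[[cls]]),
            class = "roughpnn_error_value")
    }
    if (train_counts[[cls]] < 0) {
      abort("Training counts must be non-negative.",
            class = "roughpnn_error_value")
    }
  }
  idx_train <- with_seed(as.integer(seed), {
    unlist(lapply(names(train_counts), function(cls) {
      pool <- which(data$label == cls)
      sample(pool, size = train_counts[[cls]], replace = FALSE)
    }))
  })
  idx_train <- sort(idx_train)
  train <- data[idx_train, , drop = FALSE]
  test <- data[setdiff(seq_len(nrow(data)), idx_train), , drop = FALSE]
  list(train = train, test = test)
}
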