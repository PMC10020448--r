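#' Read a Wisconsin Diagnostic Breast Cancer file
#'
#' Parses the UCI `wdbc.data` dialect: comma-separated rows of
#' `ID, diagnosis, f1, ..., f30` with no header, where the diagnosis code is
#' `M` (malignant) or `B` (benign) and the 30 features are the mean (1-10),
#' standard error (11-20) and worst (21-30) values of ten nuclear
#' measurements. The full UCI file yields 569 samples: 357 benign and 212
#' malignant.
#'
#' @param path path to a WDBC-dialect file.
#' @return A [decision_table()] with 30 attributes labeled 1-30 in file order
#'   and labels `benign`/`malignant`.
#' @export
read_wdbc <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "roughpnn_error_io")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort("WDBC file is empty.", class = "roughpnn_error_parse")
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 32L)
  if (length(bad) > 0L) {
    abort(sprintf("Line %d: expected 32 comma-separated fields, found %d.",
                  bad[1], nf[bad[1]]),
          class = "roughpnn_error_parse")
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  diag <- vapply(parts, `[[`, character(1), 2L)
  bad <- which(!diag %in% c("M", "B"))
  if (length(bad) > 0L) {
    abort(sprintf("Line %d: unknown diagnosis code '%s' (expected M or B).",
                  bad[1], diag[bad[1]]),
          class = "roughpnn_error_parse")
  }
  feats <- matrix(NA_real_, nrow = length(parts), ncol = 30L)
  for (i in seq_along(parts)) {
    v <- suppressWarnings(as.numeric(parts[[i]][3:32]))
    if (anyNA(v)) {
      abort(sprintf("Line %d: non-numeric feature value '%s'.",
                    i, parts[[i]][2L + which(is.na(v))[1]]),
            class = "roughpnn_error_parse")
    }
    feats[i, ] <- v
  }
  labels <- factor(ifelse(diag == "M", "malignant", "benign"),
                   levels = c("benign", "malignant"))
  decision_table(feats, labels, ids = ids)
}

#' Read or write a generic decision-table CSV
#'
#' The generic dialect used for synthetic tables: a header row
#' `id,label,a1,...,aK` followed by one row per sample.
#'
#' @param path file path.
#' @return For `read_decision_csv()`, a [decision_table()].
#' @export
read_decision_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("id", "label") %in% names(df))) {
    abort("Decision CSV needs `id` and `label` columns.",
          class = "roughpnn_error_parse")
  }
  acols <- grep("^a[0-9]+$", names(df), value = TRUE)
  acols <- acols[order(as.integer(sub("^a", "", acols)))]
  decision_table(as.matrix(df[acols]), df$label, ids = df$id)
}

#' @rdname read_decision_csv
#' @param data a decision table to write.
#' @export
write_decision_csv <- function(data, path) {
  validate_decision_table(data)
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
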