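#' Neighborhood granule of one sample
#'
#' The granule of sample `center` under attribute subset `B` and radius
#' `delta` is the closed Euclidean ball in the `B`-restricted feature space:
#' every sample whose distance to the center (computed over the selected
#' attributes only) is at most `delta`, boundary included. The center always
#' belongs to its own granule. Features are expected to be on a common scale
#' (see [fit_scaling()]): the radius is in scaled feature units.
#'
#' @param data a decision table.
#' @param subset integer attribute labels (non-empty subset of 1..K).
#' @param delta non-negative neighborhood radius.
#' @param center sample index (row) whose granule to build.
#' @return A list of class `granule`: `center`, `members` (sorted row
#'   indices), `subset`, `delta`.
#' @export
neighborhood <- function(data, subset, delta, center) {
  x <- feature_matrix(data, subset)
  if (delta < 0) {
    abort("`delta` must be non-negative.", class = "roughpnn_error_value")
  }
  center <- as.integer(center)
  if (center < 1L || center > nrow(x)) {
    abort("`center` is out of range.", class = "roughpnn_error_value")
  }
  d2 <- colSums((t(x) - x[center, ])^2)
  members <- which(d2 <= delta^2 + .sq_eps)
  structure(
    list(center = center, members = members,
         subset = as.integer(subset), delta = delta),
    class = "granule"
  )
}

# Boundary tolerance: distances exactly at delta are included even when the
# squared comparison picks up floating-point dust.
.sq_eps <- 1e-12

#' Granulate a whole table
#'
#' Builds the neighborhood granule of every sample. Returns a tibble so that
#' granule membership can be inspected and joined with labels directly.
#'
#' @inheritParams neighborhood
#' @return A tibble with columns `center` (row index) and `members`
#'   (list-column of sorted member indices), one row per sample.
#' @export
granulate <- function(data, subset, delta) {
  x <- feature_matrix(data, subset)
  if (delta < 0) {
    abort("`delta` must be non-negative.", class = "roughpnn_error_value")
  }
  d2 <- squared_distance_matrix(x)
  keep <- d2 <= delta^2 + .sq_eps
  tibble::tibble(
    center = seq_len(nrow(x)),
    members = lapply(seq_len(nrow(x)), function(i) which(keep[i, ]))
  )
}

# Full pairwise squared Euclidean distances, computed via the Gram expansion
# with an explicit zero diagonal (guards tiny negative round-off).
squared_distance_matrix <- function(x) {
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  d2
}

#' Granule class statistics
#'
#' Computes the three quantities that generate the loss-function matrix for a
#' target class X:
#' * `p_x`, the conditional probability `|granule ∩ X| / |granule|`;
#' * `s_x`, the significance of the granule for X — its share of X's global
#'   mass, `|granule ∩ X| / |X|`;
#' * `s_c`, the complement significance `|granule ∩ X^C| / |X^C|`.
#'
#' Both significances read the granule against the global class distribution
#' of the original data, so they require each class to be non-empty overall.
#'
#' @param granule a `granule` from [neighborhood()], or a plain integer vector
#'   of member indices.
#' @param labels the per-sample label vector of the full table.
#' @param target the class X of interest (a label level).
#' @return A one-row tibble with columns `p_x`, `s_x`, `s_c`.
#' @export
granule_stats <- function(granule, labels, target) {
  members <- if (inherits(granule, "granule")) granule$members else as.integer(granule)
  in_x <- labels == target
  n_x <- sum(in_x)
  n_c <- sum(!in_x)
  if (n_x == 0L || n_c == 0L) {
    abort("Granule statistics need both the target class and its complement to be non-empty globally.",
          class = "roughpnn_error_value")
  }
  cx <- sum(in_x[members])
  tibble::tibble(
    p_x = cx / length(members),
    s_x = cx / n_x,
    s_c = (length(members) - cx) / n_c
  )
}
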