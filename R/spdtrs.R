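#' Loss-function matrix from granule statistics
#'
#' Generates the six decision-theoretic losses from a granule's class
#' statistics and the single compensation coefficient `xi`. The costs of the
#' two correct actions are fixed at zero (`lambda_pp = lambda_nn = 0`); the
#' remaining four are generated from the granule's conditional probability
#' `p_x` and the significances `s_x`, `s_c`:
#'
#' * `lambda_bp = s_x * (p_x - xi)` — deferring on a true X member,
#' * `lambda_bn = s_c * (1 - p_x - xi)` — deferring on a true non-member,
#' * `lambda_pn = s_c` — accepting a non-member,
#' * `lambda_np = s_x` — rejecting a member.
#'
#' The two boundary losses are clamped at zero when their parenthesized factor
#' goes negative (e.g. `p_x < xi`): negative losses would break the Bayes-risk
#' ordering of the three actions.
#'
#' @param stats a one-row data frame (or named list) with `p_x`, `s_x`, `s_c`,
#'   as returned by [granule_stats()].
#' @param xi compensation coefficient; the decision-maker's tolerance of
#'   uncertainty, valid range `(0, 0.4]` (values above 0.4 warn).
#' @return A one-row tibble of class `loss_matrix` with the six lambdas and
#'   `xi`.
#' @export
loss_matrix <- function(stats, xi) {
  if (!is.numeric(xi) || length(xi) != 1L || xi <= 0) {
    abort("`xi` must be a single positive number.", class = "roughpnn_error_value")
  }
  if (xi > 0.4) {
    warn("`xi` above 0.4 is outside the recommended range (0, 0.4].")
  }
  p <- stats$p_x
  s <- stats$s_x
  sc <- stats$s_c
  out <- tibble::tibble(
    lambda_pp = 0,
    lambda_bp = pmax(0, s * (p - xi)),
    lambda_np = s,
    lambda_pn = sc,
    lambda_bn = pmax(0, sc * (1 - p - xi)),
    lambda_nn = 0,
    xi = xi
  )
  class(out) <- c("loss_matrix", class(out))
  out
}

#' Decision thresholds from a loss matrix
#'
#' Derives the three-way decision thresholds by the standard Bayes
#' minimum-risk comparison of the accept/defer/reject actions:
#' `alpha = (l_PN - l_BN) / ((l_PN - l_BN) + (l_BP - l_PP))` and
#' `beta = (l_BN - l_NN) / ((l_BN - l_NN) + (l_NP - l_BP))`.
#'
#' The derivation is well-posed only under the strict loss ordering
#' `l_PP < l_BP < l_NP` and `l_NN < l_BN < l_PN`. When that fails (a clamped
#' boundary loss, a zero denominator, or `beta >= alpha`) the pair is
#' degenerate: both thresholds collapse to the two-way cut
#' `gamma = (l_PN - l_NN) / ((l_PN - l_NN) + (l_NP - l_PP))` and the boundary
#' region is empty.
#'
#' @param lm a one-row `loss_matrix`.
#' @return A one-row tibble with `alpha`, `beta` and a logical `degenerate`
#'   flag; when degenerate, `alpha == beta == gamma`.
#' @export
decision_thresholds <- function(lm) {
  den_a <- (lm$lambda_pn - lm$lambda_bn) + (lm$lambda_bp - lm$lambda_pp)
  den_b <- (lm$lambda_bn - lm$lambda_nn) + (lm$lambda_np - lm$lambda_bp)
  ok <- lm$lambda_bp > lm$lambda_pp && lm$lambda_bn > lm$lambda_nn &&
    den_a > 0 && den_b > 0
  if (ok) {
    alpha <- (lm$lambda_pn - lm$lambda_bn) / den_a
    beta <- (lm$lambda_bn - lm$lambda_nn) / den_b
    ok <- beta < alpha
    if (ok) {
      return(tibble::tibble(alpha = alpha, beta = beta, degenerate = FALSE))
    }
  }
  gden <- (lm$lambda_pn - lm$lambda_nn) + (lm$lambda_np - lm$lambda_pp)
  gam <- if (gden > 0) (lm$lambda_pn - lm$lambda_nn) / gden else 0.5
  tibble::tibble(alpha = gam, beta = gam, degenerate = TRUE)
}

# Vectorized per-granule risk engine.
#
# Given the membership matrix `keep` (n x n, keep[i, j] = sample j belongs to
# the granule of sample i) and the 0/1 indicator of the target class,
# computes granule-local statistics, generated losses, thresholds, regions
# and the summed Bayes risk for that class.
class_region_risk <- function(keep, in_x, xi) {
  n <- length(in_x)
  n_x <- sum(in_x)
  n_c <- n - n_x
  sz <- rowSums(keep)
  cx <- as.vector(keep %*% in_x)
  p <- cx / sz
  s <- cx / n_x
  sc <- (sz - cx) / n_c
  lbp <- pmax(0, s * (p - xi))
  lbn <- pmax(0, sc * (1 - p - xi))
  lpn <- sc
  lnp <- s
  # three-way thresholds where the loss ordering is strict; two-way gamma
  # elsewhere (see decision_thresholds())
  den_a <- (lpn - lbn) + lbp
  den_b <- lbn + (lnp - lbp)
  ok <- lbp > 0 & lbn > 0 & den_a > 0 & den_b > 0
  alpha <- ifelse(ok, (lpn - lbn) / den_a, NA_real_)
  beta <- ifelse(ok, lbn / den_b, NA_real_)
  ok <- ok & !is.na(alpha) & !is.na(beta) & beta < alpha
  gden <- lpn + lnp
  gam <- ifelse(gden > 0, lpn / gden, 0.5)
  alpha <- ifelse(ok, alpha, gam)
  beta <- ifelse(ok, beta, gam)
  region <- ifelse(p >= alpha, "POS", ifelse(p <= beta, "NEG", "BND"))
  term <- ifelse(region == "POS", (1 - p) * lpn,
                 ifelse(region == "NEG", p * lnp,
                        p * lbp + (1 - p) * lbn))
  list(region = region, risk = sum(term), p = p, alpha = alpha, beta = beta)
}

# Membership matrix for subset B at radius delta, optionally from a
# precomputed squared-distance matrix.
membership_matrix <- function(data, subset, delta, d2 = NULL) {
  if (is.null(d2)) {
    d2 <- squared_distance_matrix(feature_matrix(data, subset))
  }
  d2 <= delta^2 + .sq_eps
}

#' Three-way region assignment
#'
#' Places every sample into the positive, boundary or negative region of the
#' target class by comparing its granule-local conditional probability with
#' its granule-local thresholds: POS if `p >= alpha`, NEG if `p <= beta`, BND
#' otherwise. A probability exactly at `alpha` is accepted (tie goes to the
#' less risky acceptance).
#'
#' @inheritParams granulate
#' @param xi compensation coefficient in `(0, 0.4]`.
#' @param target the class X; defaults to the first label level.
#' @return A tibble with one row per sample: `sample`, `p`, `alpha`, `beta`,
#'   `region` (factor POS/BND/NEG).
#' @export
assign_regions <- function(data, subset, delta, xi, target = levels(data$label)[1]) {
  validate_decision_table(data)
  check_xi(xi)
  keep <- membership_matrix(data, subset, delta)
  in_x <- as.numeric(data$label == target)
  if (sum(in_x) == 0 || sum(in_x) == length(in_x)) {
    abort("Region assignment needs both the target class and its complement present.",
          class = "roughpnn_error_value")
  }
  res <- class_region_risk(keep, in_x, xi)
  tibble::tibble(
    sample = seq_len(nrow(data)),
    p = res$p,
    alpha = res$alpha,
    beta = res$beta,
    region = factor(res$region, levels = c("POS", "BND", "NEG"))
  )
}

#' Overall Bayes risk of an attribute subset
#'
#' The overall risk of deciding with attribute subset `B` at radius `delta`
#' sums, over all samples, the expected loss of the region each sample landed
#' in: `(1 - p) * l_PN` in the positive region, `p * l_BP + (1 - p) * l_BN`
#' in the boundary, and `p * l_NP` in the negative region, with all
#' quantities granule-local. For multi-class tables the risk is computed
#' one-vs-rest per nominal class and summed; `target` restricts it to a
#' single class.
#'
#' @inheritParams assign_regions
#' @param target optional single class; default sums one-vs-rest risks over
#'   all classes.
#' @return A non-negative scalar risk.
#' @export
bayes_risk <- function(data, subset, delta, xi, target = NULL) {
  validate_decision_table(data)
  check_xi(xi)
  keep <- membership_matrix(data, subset, delta)
  risk_from_membership(keep, data$label, xi, target)
}

risk_from_membership <- function(keep, labels, xi, target = NULL) {
  classes <- target %||% levels(factor(labels))
  total <- 0
  for (cls in classes) {
    in_x <- as.numeric(labels == cls)
    if (sum(in_x) == 0 || sum(in_x) == length(in_x)) {
      abort("Bayes risk needs at least one sample inside and outside each class.",
            class = "roughpnn_error_value")
    }
    total <- total + class_region_risk(keep, in_x, xi)$risk
  }
  total
}

check_xi <- function(xi) {
  if (!is.numeric(xi) || length(xi) != 1L || xi <= 0) {
    abort("`xi` must be a single positive number.", class = "roughpnn_error_value")
  }
  if (xi > 0.4) {
    warn("`xi` above 0.4 is outside the recommended range (0, 0.4].")
  }
  invisible(xi)
}
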