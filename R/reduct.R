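#' Risk-based attribute reduction
#'
#' Searches for an attribute subset `B` whose overall Bayes risk is no worse
#' than that of the full attribute set `C`, and which is minimal: every
#' proper subset of `B` carries strictly greater risk. The search is greedy
#' forward selection — start from the single attribute of minimal risk, then
#' repeatedly add the attribute giving the largest risk decrease until no
#' addition helps — followed by a backward pass that drops any attribute
#' whose removal does not increase the risk. When the surviving subset is
#' small (at most `minimality_limit` attributes) an exact refinement
#' enumerates all of its subsets and keeps the one of minimal risk, breaking
#' ties by cardinality and then by lowest attribute labels, which guarantees
#' full minimality on small reducts. Ties everywhere go to the lowest
#' attribute label.
#'
#' Risk comparisons use a small numerical tolerance, and the "lower risk than
#' `C`" admission is non-strict: on a consistent table every informative
#' subset ties the full set at zero risk, and the meaningful reduct is the
#' smallest subset attaining it.
#'
#' If no subset attains the full-set risk the full attribute set is returned
#' with a warning (`no_reduct = TRUE`).
#'
#' @inheritParams bayes_risk
#' @param minimality_limit largest reduct size for which the exact
#'   subset-enumeration refinement runs (default 10).
#' @param tol absolute tolerance for risk comparisons.
#' @return An object of class `spdtrs_reduct`: a list with `selected`
#'   (attribute labels in selection order), `risk`, `risk_C`, `xi`, `delta`,
#'   `no_reduct`, and `trace` (a tibble of accepted search steps).
#' @seealso [exhaustive_reduct()] for the brute-force oracle on small tables.
#' @export
reduce_attributes <- function(data, xi = 0.25, delta = 0.15, target = NULL,
                              minimality_limit = 10L, tol = 1e-8) {
  validate_decision_table(data, require_all_classes = TRUE)
  check_xi(xi)
  k <- n_attributes(data)
  if (k < 2L) {
    abort("Attribute reduction needs at least 2 attributes.",
          class = "roughpnn_error_value")
  }
  stack <- attribute_sq_stack(data)
  labels <- data$label
  dd <- delta^2 + .sq_eps
  eval_d2 <- function(d2) {
    risk_from_membership(d2 <= dd, labels, xi, target)
  }
  risk_C <- eval_d2(Reduce(`+`, stack))

  trace <- list()
  push <- function(action, attribute, risk) {
    trace[[length(trace) + 1L]] <<- tibble::tibble(
      action = action, attribute = attribute, risk = risk)
  }

  # forward pass
  selected <- integer(0)
  base <- matrix(0, nrow(data), nrow(data))
  current <- Inf
  repeat {
    cands <- setdiff(seq_len(k), selected)
    if (length(cands) == 0L) break
    risks <- vapply(cands, function(a) eval_d2(base + stack[[a]]), numeric(1))
    best <- cands[order(risks, cands)][1]
    best_risk <- min(risks)
    accept <- if (length(selected) == 0L) TRUE else best_risk < current - tol
    if (!accept) break
    selected <- c(selected, best)
    base <- base + stack[[best]]
    current <- best_risk
    push("add", best, current)
    if (current <= tol) break
  }

  # if the greedy path stalled above the full-set risk, fall back to
  # backward elimination from C, which can only end at or below risk_C
  if (current > risk_C + tol) {
    selected <- seq_len(k)
    base <- Reduce(`+`, stack)
    current <- risk_C
    push("restart_from_C", NA_integer_, current)
  }

  # backward pass: drop attributes whose removal does not increase risk
  repeat {
    dropped <- FALSE
    for (a in sort(selected)) {
      if (length(selected) == 1L) break
      r <- eval_d2(base - stack[[a]])
      if (r <= current + tol) {
        selected <- setdiff(selected, a)
        base <- base - stack[[a]]
        current <- r
        push("drop", a, current)
        dropped <- TRUE
      }
    }
    if (!dropped) break
  }

  # exact minimality refinement on small reducts
  if (length(selected) > 1L && length(selected) <= minimality_limit) {
    risks <- subset_risks(stack, sort(selected), labels, xi, dd, target)
    pick <- pick_minimal(risks, tol)
    if (!setequal(pick$subset, selected)) {
      selected <- selected[selected %in% pick$subset]
      current <- pick$risk
      push("refine", NA_integer_, current)
    } else {
      current <- min(current, pick$risk)
    }
  }

  no_reduct <- current > risk_C + tol
  if (no_reduct) {
    warn("No attribute subset attains the full-set risk; returning the full attribute set.")
    selected <- seq_len(k)
    current <- risk_C
  }
  new_reduct(selected, current, risk_C, xi, delta,
             dplyr::bind_rows(trace), no_reduct, method = "greedy")
}

#' Exhaustive reduct oracle
#'
#' Enumerates every non-empty attribute subset, computes its overall Bayes
#' risk, and returns the minimal-risk subset that (1) is no worse than the
#' full set and (2) has strictly greater risk on every proper non-empty
#' subset, under the documented tie rule (minimal risk, then minimal
#' cardinality, then lowest attribute labels). Intended as a test oracle on
#' small tables; refuses more than `max_attributes` attributes.
#'
#' @inheritParams reduce_attributes
#' @param max_attributes hard cap on table width (at most 10).
#' @return An object of class `spdtrs_reduct` whose `trace` holds the risk of
#'   every enumerated subset.
#' @export
exhaustive_reduct <- function(data, xi = 0.25, delta = 0.15, target = NULL,
                              max_attributes = 10L, tol = 1e-8) {
  validate_decision_table(data, require_all_classes = TRUE)
  check_xi(xi)
  k <- n_attributes(data)
  max_attributes <- min(as.integer(max_attributes), 10L)
  if (k > max_attributes) {
    abort(sprintf("Exhaustive enumeration refused: %d attributes exceeds the cap of %d.",
                  k, max_attributes),
          class = "roughpnn_error_value")
  }
  stack <- attribute_sq_stack(data)
  dd <- delta^2 + .sq_eps
  risks <- subset_risks(stack, seq_len(k), data$label, xi, dd, target)
  full_mask <- bitwShiftL(1L, k) - 1L
  risk_C <- risks$risk[risks$mask == full_mask]

  if (k == 1L) {
    return(new_reduct(1L, risk_C, risk_C, xi, delta,
                      tibble::tibble(action = "enumerate", attribute = 1L, risk = risk_C),
                      no_reduct = FALSE, method = "exhaustive"))
  }

  risk_by_mask <- numeric(full_mask)
  risk_by_mask[risks$mask] <- risks$risk
  admissible <- logical(full_mask)
  for (m in risks$mask) {
    if (risk_by_mask[m] > risk_C + tol) next
    ok <- TRUE
    sub <- bitwAnd(m - 1L, m)
    while (sub > 0L) {
      if (risk_by_mask[sub] <= risk_by_mask[m] + tol) {
        ok <- FALSE
        break
      }
      sub <- bitwAnd(sub - 1L, m)
    }
    admissible[m] <- ok
  }
  trace <- tibble::tibble(action = "enumerate", attribute = NA_integer_,
                          risk = risks$risk, mask = risks$mask,
                          admissible = admissible[risks$mask])
  if (!any(admissible)) {
    warn("No admissible subset found; returning the full attribute set.")
    return(new_reduct(seq_len(k), risk_C, risk_C, xi, delta, trace,
                      no_reduct = TRUE, method = "exhaustive"))
  }
  cand <- risks[admissible[risks$mask], , drop = FALSE]
  pick <- pick_minimal(cand, tol)
  new_reduct(sort(pick$subset), pick$risk, risk_C, xi, delta, trace,
             no_reduct = FALSE, method = "exhaustive")
}

# One n x n squared-difference matrix per attribute, so that the squared
# distance matrix of any subset is the sum of its per-attribute layers.
attribute_sq_stack <- function(data) {
  x <- feature_matrix(data)
  lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    outer(v, v, function(a, b) (a - b)^2)
  })
}

# Risks of every non-empty subset of `attrs`, sharing prefix distance sums
# through recursion. Returns a tibble with list-column `subset`, `risk`, and
# a bitmask over positions in `attrs`.
subset_risks <- function(stack, attrs, labels, xi, dd, target) {
  n <- nrow(stack[[1]])
  subsets <- list()
  risks <- numeric(0)
  masks <- integer(0)
  recurse <- function(i, d2, chosen, mask) {
    if (i > length(attrs)) {
      if (length(chosen) > 0L) {
        subsets[[length(subsets) + 1L]] <<- chosen
        risks[length(risks) + 1L] <<- risk_from_membership(d2 <= dd, labels, xi, target)
        masks[length(masks) + 1L] <<- mask
      }
      return(invisible(NULL))
    }
    recurse(i + 1L, d2, chosen, mask)
    recurse(i + 1L, d2 + stack[[attrs[i]]], c(chosen, attrs[i]),
            bitwOr(mask, bitwShiftL(1L, i - 1L)))
  }
  recurse(1L, matrix(0, n, n), integer(0), 0L)
  tibble::tibble(subset = subsets, risk = risks, mask = masks)
}

# Tie rule shared by the refinement and the oracle: minimal risk (within
# tol), then minimal cardinality, then lexicographically lowest labels.
pick_minimal <- function(risks, tol) {
  near <- which(risks$risk <= min(risks$risk) + tol)
  sizes <- lengths(risks$subset[near])
  near <- near[sizes == min(sizes)]
  if (length(near) > 1L) {
    keys <- vapply(risks$subset[near], function(s) {
      paste(sprintf("%06d", sort(s)), collapse = ",")
    }, character(1))
    near <- near[order(keys)]
  }
  list(subset = sort(risks$subset[[near[1]]]), risk = risks$risk[near[1]])
}

new_reduct <- function(selected, risk, risk_C, xi, delta, trace, no_reduct,
                       method) {
  structure(
    list(selected = as.integer(selected), risk = risk, risk_C = risk_C,
         xi = xi, delta = delta, trace = trace, no_reduct = no_reduct,
         method = method),
    class = "spdtrs_reduct"
  )
}

#' @export
print.spdtrs_reduct <- function(x, ...) {
  cat(sprintf("<spdtrs_reduct> %s search, xi = %g, delta = %g\n",
              x$method, x$xi, x$delta))
  cat(sprintf("  selected %d attribute(s): {%s}\n",
              length(x$selected), paste(x$selected, collapse = ",")))
  cat(sprintf("  risk(B) = %.6g vs risk(C) = %.6g%s\n",
              x$risk, x$risk_C, if (x$no_reduct) "  [no reduct found]" else ""))
  invisible(x)
}

#' Serialize a reduct to JSON
#'
#' Writes `{selected, risk_B, risk_C, xi, delta, trace}` for downstream
#' tooling.
#'
#' @param reduct an `spdtrs_reduct`.
#' @param path output file.
#' @export
write_reduct_json <- function(reduct, path) {
  obj <- list(
    selected = reduct$selected,
    risk_B = reduct$risk,
    risk_C = reduct$risk_C,
    xi = reduct$xi,
    delta = reduct$delta,
    no_reduct = reduct$no_reduct,
    trace = reduct$trace[c("action", "attribute", "risk")]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
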