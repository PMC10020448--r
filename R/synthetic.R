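#' Specification of a synthetic two-class table
#'
#' Describes a seeded generator of WBCD-like tables: class-conditional
#' Gaussian informative attributes, redundant attributes built from the
#' informative ones, and pure-noise attributes independent of the class.
#' With known ground-truth attribute roles, attribute reduction and
#' classification become testable without any download.
#'
#' @param n_per_class named vector, class label -> sample count.
#' @param k_informative number of informative attributes; their
#'   class-conditional means are `class_separation` within-class standard
#'   deviations apart (per dimension, unit within-class SD).
#' @param k_redundant number of redundant attributes derived from the
#'   informative block plus Gaussian noise with SD `redundancy_noise_sd`.
#' @param k_noise number of pure-noise attributes (standard Gaussian,
#'   class-independent).
#' @param class_separation distance between class means per informative
#'   dimension, in within-class SD units. 0 makes the label independent of
#'   every attribute.
#' @param redundancy_noise_sd SD of the noise added to redundant attributes.
#' @param redundancy_style `"random"` draws each redundant attribute as a
#'   random linear combination of all informative ones; `"paired"` ties each
#'   redundant attribute to a single informative parent (cycling), emulating
#'   the mean/SE/worst triplet structure of the Wisconsin features.
#' @param seed integer generator seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class, k_informative = 2L, k_redundant = 0L,
                           k_noise = 0L, class_separation = 3,
                           redundancy_noise_sd = 0.5,
                           redundancy_style = c("random", "paired"),
                           seed = 1L) {
  redundancy_style <- match.arg(redundancy_style)
  if (is.null(names(n_per_class)) || length(n_per_class) < 2L ||
      any(n_per_class < 1)) {
    abort("`n_per_class` must be a named vector of >= 2 positive class counts.",
          class = "roughpnn_error_value")
  }
  if (k_informative < 0 || k_redundant < 0 || k_noise < 0) {
    abort("Attribute counts must be non-negative.", class = "roughpnn_error_value")
  }
  if (class_separation > 0 && k_informative < 1) {
    abort("Need at least one informative attribute when `class_separation` > 0.",
          class = "roughpnn_error_value")
  }
  if (k_informative + k_redundant + k_noise < 1) {
    abort("The table needs at least one attribute.", class = "roughpnn_error_value")
  }
  if (k_redundant > 0 && k_informative < 1) {
    abort("Redundant attributes need an informative block to derive from.",
          class = "roughpnn_error_value")
  }
  structure(
    list(n_per_class = n_per_class, k_informative = as.integer(k_informative),
         k_redundant = as.integer(k_redundant), k_noise = as.integer(k_noise),
         class_separation = class_separation,
         redundancy_noise_sd = redundancy_noise_sd,
         redundancy_style = redundancy_style, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' WBCD-like synthetic specification
#'
#' A 30-attribute, 569-sample stand-in for the Wisconsin Diagnostic Breast
#' Cancer table: 357 benign and 212 malignant samples, attributes organized
#' as 10 correlated triplets (one informative parent in positions 1-10, two
#' paired redundant children in 11-20 and 21-30) emulating the mean /
#' standard-error / worst layout. Separation of 1.2 SD per informative
#' dimension gives roughly the difficulty of the real data (a few percent
#' Bayes error over 10 informative dimensions).
#'
#' @param seed generator seed (default 42).
#' @return A `synthetic_spec`.
#' @export
wbcd_like_spec <- function(seed = 42L) {
  synthetic_spec(
    n_per_class = c(benign = 357L, malignant = 212L),
    k_informative = 10L, k_redundant = 20L, k_noise = 0L,
    class_separation = 1.2, redundancy_noise_sd = 0.5,
    redundancy_style = "paired", seed = seed
  )
}

#' Generate a synthetic decision table
#'
#' Draws a table from a [synthetic_spec()]. Informative attributes are
#' class-conditional Gaussians with unit within-class SD and means
#' `class_separation` apart per dimension; redundant attributes are linear
#' functions of the informative block plus Gaussian noise; noise attributes
#' are standard Gaussians independent of the class. The same seed always
#' yields an identical table. Ground-truth attribute roles are attached as
#' the `"attribute_roles"` attribute (see [attribute_roles()]).
#'
#' @param spec a `synthetic_spec`.
#' @return A [decision_table()] with
#'   `k_informative + k_redundant + k_noise` attributes, informative first,
#'   then redundant, then noise.
#' @export
generate_table <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    abort("`spec` must be a synthetic_spec.", class = "roughpnn_error_value")
  }
  classes <- names(spec$n_per_class)
  n <- sum(spec$n_per_class)
  ki <- spec$k_informative
  kr <- spec$k_redundant
  kn <- spec$k_noise
  with_seed(spec$seed, {
    labels <- factor(rep(classes, times = spec$n_per_class), levels = classes)
    # centered class offsets so separation is the gap between adjacent means
    offs <- (seq_along(classes) - (length(classes) + 1) / 2) * spec$class_separation
    x <- matrix(0, n, ki + kr + kn)
    if (ki > 0) {
      mu <- offs[as.integer(labels)]
      x[, seq_len(ki)] <- matrix(rnorm(n * ki), n, ki) + mu
    }
    if (kr > 0) {
      if (spec$redundancy_style == "paired") {
        parents <- ((seq_len(kr) - 1L) %% ki) + 1L
        w <- matrix(0, ki, kr)
        w[cbind(parents, seq_len(kr))] <- stats::runif(kr, 0.5, 1.5)
      } else {
        w <- matrix(rnorm(ki * kr), ki, kr)
        w <- sweep(w, 2, sqrt(colSums(w^2)), "/")
      }
      x[, ki + seq_len(kr)] <- x[, seq_len(ki), drop = FALSE] %*% w +
        matrix(rnorm(n * kr, sd = spec$redundancy_noise_sd), n, kr)
    }
    if (kn > 0) {
      x[, ki + kr + seq_len(kn)] <- matrix(rnorm(n * kn), n, kn)
    }
    out <- decision_table(x, labels)
    attr(out, "attribute_roles") <- rep(
      c("informative", "redundant", "noise"), times = c(ki, kr, kn))
    out
  })
}

#' Ground-truth attribute roles of a synthetic table
#'
#' @param data a table from [generate_table()].
#' @return A tibble with `attribute` and `role`
#'   (informative/redundant/noise).
#' @export
attribute_roles <- function(data) {
  roles <- attr(data, "attribute_roles")
  if (is.null(roles)) {
    abort("No attribute roles attached; was this table generated by generate_table()?",
          class = "roughpnn_error_value")
  }
  tibble::tibble(attribute = seq_along(roles), role = roles)
}

#' Write the ground-truth roles sidecar
#'
#' JSON sidecar accompanying a synthetic CSV, recording which attributes are
#' informative, redundant and noise.
#'
#' @param data a table from [generate_table()].
#' @param path output JSON path.
#' @export
write_roles_json <- function(data, path) {
  roles <- attribute_roles(data)
  jsonlite::write_json(as.list(split(roles$attribute, roles$role)), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}
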