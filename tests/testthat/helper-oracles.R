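# Independent brute-force oracles, written as plain loops so they share no
# code path with the package internals.

# random two-class table with uniform [0,1] features
random_table <- function(seed, n, k, classes = c("u", "v")) {
  set.seed(seed)
  repeat {
    labels <- sample(classes, n, replace = TRUE)
    if (length(unique(labels)) == length(classes)) break
  }
  decision_table(matrix(runif(n * k), n, k), factor(labels, levels = classes))
}

table_features <- function(data) {
  as.matrix(data[grep("^a[0-9]+$", names(data), value = TRUE)])
}

# neighborhood membership by explicit pairwise loop
naive_members <- function(data, subset, delta, center) {
  x <- table_features(data)[, subset, drop = FALSE]
  out <- integer(0)
  for (j in seq_len(nrow(x))) {
    d <- sqrt(sum((x[center, ] - x[j, ])^2))
    if (d <= delta + 1e-9) out <- c(out, j)
  }
  out
}

naive_stats <- function(members, labels, target) {
  inx <- sum(labels[members] == target)
  list(
    p = inx / length(members),
    s = inx / sum(labels == target),
    sc = (length(members) - inx) / sum(labels != target)
  )
}

# Table-1 losses with clamping, threshold closed forms with two-way fallback
naive_lambdas <- function(st, xi) {
  list(
    bp = max(0, st$s * (st$p - xi)),
    bn = max(0, st$sc * (1 - st$p - xi)),
    pn = st$sc,
    np = st$s
  )
}

naive_region <- function(st, xi) {
  l <- naive_lambdas(st, xi)
  three_way <- l$bp > 0 && l$bn > 0
  if (three_way) {
    alpha <- (l$pn - l$bn) / ((l$pn - l$bn) + l$bp)
    beta <- l$bn / (l$bn + (l$np - l$bp))
    three_way <- is.finite(alpha) && is.finite(beta) && beta < alpha
  }
  if (!three_way) {
    gam <- if (l$pn + l$np > 0) l$pn / (l$pn + l$np) else 0.5
    alpha <- gam
    beta <- gam
  }
  if (st$p >= alpha) "POS" else if (st$p <= beta) "NEG" else "BND"
}

naive_risk_one_class <- function(data, subset, delta, xi, target) {
  labels <- data$label
  total <- 0
  for (i in seq_len(nrow(data))) {
    members <- naive_members(data, subset, delta, i)
    st <- naive_stats(members, labels, target)
    l <- naive_lambdas(st, xi)
    region <- naive_region(st, xi)
    total <- total + switch(region,
      POS = (1 - st$p) * l$pn,
      BND = st$p * l$bp + (1 - st$p) * l$bn,
      NEG = st$p * l$np
    )
  }
  total
}

naive_risk <- function(data, subset, delta, xi) {
  sum(vapply(levels(data$label), function(cls) {
    naive_risk_one_class(data, subset, delta, xi, cls)
  }, numeric(1)))
}

# 1-nearest-neighbor label by explicit scan
nn1_predict <- function(xtr, ytr, xq) {
  best <- 1L
  bestd <- Inf
  for (j in seq_len(nrow(xtr))) {
    d <- sum((xq - xtr[j, ])^2)
    if (d < bestd) {
      bestd <- d
      best <- j
    }
  }
  as.character(ytr[best])
}

# small perfectly separated two-class table (1-D gap >> any delta used)
separated_table <- function(n_each = 5) {
  decision_table(
    matrix(c(seq(0, 0.1, length.out = n_each),
             seq(0.8, 0.9, length.out = n_each)), ncol = 1),
    factor(rep(c("u", "v"), each = n_each), levels = c("u", "v"))
  )
}

# write a toy WDBC-dialect file; returns path
write_toy_wdbc <- function(path, rows = NULL) {
  if (is.null(rows)) {
    rows <- vapply(1:3, function(i) {
      paste(c(8000 + i, c("M", "B", "B")[i],
              sprintf("%.3f", seq(i, i + 2.9, by = 0.1))), collapse = ",")
    }, character(1))
  }
  writeLines(rows, path)
  path
}
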