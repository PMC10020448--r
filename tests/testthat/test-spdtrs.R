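# 4-sample 1-D worked table: granules at delta 0.15 are {1,2}, {1,2,3},
# {2,3}, {4}; one-vs-rest risk summed over both classes is 7/12 (hand
# evaluation of each region term, frozen below).
worked_table <- function() {
  decision_table(matrix(c(0, 0.1, 0.2, 0.6), ncol = 1),
                 factor(c("A", "A", "B", "B"), levels = c("A", "B")))
}

test_that("loss matrix follows the generated-lambda formulas with clamping", {
  st <- tibble::tibble(p_x = 0.6, s_x = 0.5, s_c = 0.25)
  lm <- loss_matrix(st, xi = 0.25)
  expect_equal(lm$lambda_pp, 0)
  expect_equal(lm$lambda_nn, 0)
  expect_equal(lm$lambda_bp, 0.175)   # 0.5 * (0.6 - 0.25)
  expect_equal(lm$lambda_bn, 0.0375)  # 0.25 * (1 - 0.6 - 0.25)
  expect_equal(lm$lambda_pn, 0.25)
  expect_equal(lm$lambda_np, 0.5)

  # vanishing factor at p = xi, clamping below
  expect_equal(loss_matrix(tibble::tibble(p_x = 0.25, s_x = 1, s_c = 1), 0.25)$lambda_bp, 0)
  expect_equal(loss_matrix(tibble::tibble(p_x = 0.1, s_x = 1, s_c = 1), 0.25)$lambda_bp, 0)

  expect_error(loss_matrix(st, 0), class = "roughpnn_error_value")
  expect_warning(loss_matrix(st, 0.45), "0.4")
})

test_that("decision thresholds match the closed forms and algebraic identities", {
  lm <- loss_matrix(tibble::tibble(p_x = 0.6, s_x = 0.5, s_c = 0.25), 0.25)
  th <- decision_thresholds(lm)
  expect_false(th$degenerate)
  expect_equal(th$alpha, 0.2125 / 0.3875)
  expect_equal(th$beta, 0.0375 / 0.3625)
  expect_lt(th$beta, th$alpha)

  # symmetric losses: alpha + beta = 1
  sym <- tibble::tibble(lambda_pp = 0, lambda_bp = 0.2, lambda_np = 0.7,
                        lambda_pn = 0.7, lambda_bn = 0.2, lambda_nn = 0)
  th_sym <- decision_thresholds(sym)
  expect_equal(th_sym$alpha + th_sym$beta, 1)

  # boundary loss collapsing onto a correct-action loss degenerates to two-way
  deg <- tibble::tibble(lambda_pp = 0, lambda_bp = 0, lambda_np = 0.5,
                        lambda_pn = 0.5, lambda_bn = 0.2, lambda_nn = 0)
  th_deg <- decision_thresholds(deg)
  expect_true(th_deg$degenerate)
  expect_equal(th_deg$alpha, th_deg$beta)
})

test_that("regions partition the universe and match the brute-force oracle", {
  # perfectly separated classes, small delta: empty boundary
  tbl <- separated_table()
  reg <- assign_regions(tbl, 1, 0.1, 0.25, target = "u")
  expect_equal(sum(reg$region == "BND"), 0L)
  expect_setequal(reg$sample[reg$region == "POS"], which(tbl$label == "u"))
  expect_setequal(reg$sample[reg$region == "NEG"], which(tbl$label == "v"))

  for (seed in 20:25) {
    tblr <- random_table(seed, 12, 3)
    delta <- runif(1, 0.1, 0.5)
    xi <- runif(1, 0.05, 0.4)
    reg <- assign_regions(tblr, 1:3, delta, xi, target = "u")
    expect_equal(sort(reg$sample), 1:12) # partition
    want <- vapply(1:12, function(i) {
      naive_region(naive_stats(naive_members(tblr, 1:3, delta, i),
                               tblr$label, "u"), xi)
    }, character(1))
    expect_equal(as.character(reg$region), want,
                 info = sprintf("seed %d", seed))
  }
})

test_that("overall Bayes risk reproduces hand-computed and oracle values", {
  # consistent table, pure granules: every term vanishes
  expect_equal(bayes_risk(separated_table(), 1, 0.1, 0.25), 0)

  # frozen hand evaluation: per-class risk 7/24, both classes 7/12
  wt <- worked_table()
  expect_equal(bayes_risk(wt, 1, 0.15, 0.25, target = "A"), 7 / 24)
  expect_equal(bayes_risk(wt, 1, 0.15, 0.25, target = "B"), 7 / 24)
  expect_equal(bayes_risk(wt, 1, 0.15, 0.25), 7 / 12)

  # random tables: non-negative and equal to the loop oracle
  for (seed in 30:35) {
    tbl <- random_table(seed, 11, 4)
    delta <- runif(1, 0.1, 0.6)
    xi <- runif(1, 0.05, 0.4)
    b <- sort(sample(1:4, sample(2:4, 1)))
    r <- bayes_risk(tbl, b, delta, xi)
    expect_gte(r, 0)
    expect_equal(r, naive_risk(tbl, b, delta, xi), tolerance = 1e-10,
                 info = sprintf("seed %d", seed))
  }
})

test_that("greedy reduction selects the separating attribute and drops noise", {
  set.seed(99)
  x_sep <- c(runif(8, 0, 0.1), runif(8, 0.8, 1))
  tbl <- decision_table(cbind(x_sep, runif(16)),
                        factor(rep(c("u", "v"), each = 8)))
  red <- reduce_attributes(tbl, xi = 0.25, delta = 0.15)
  expect_equal(red$selected, 1L)
  expect_false(red$no_reduct)
  expect_lte(red$risk, red$risk_C + 1e-8)

  # duplicated attribute: at most one copy selected
  tbl_dup <- decision_table(cbind(x_sep, x_sep), factor(rep(c("u", "v"), each = 8)))
  red_dup <- reduce_attributes(tbl_dup, xi = 0.25, delta = 0.15)
  expect_length(red_dup$selected, 1L)

  # accepted trace risks are non-increasing
  tblr <- random_table(42, 25, 6)
  redr <- reduce_attributes(tblr, xi = 0.2, delta = 0.3)
  steps <- tidy(redr)
  restarts <- which(steps$action == "restart_from_C")
  from <- if (length(restarts) > 0) max(restarts) + 1L else 1L
  kept <- steps$risk[seq(from, nrow(steps))]
  expect_true(all(diff(kept) <= 1e-8))

  expect_error(reduce_attributes(random_table(1, 10, 1), 0.25, 0.15),
               class = "roughpnn_error_value")
})

test_that("exhaustive oracle handles degenerate widths and redundancy", {
  # single attribute: no proper subset exists, the full set comes back
  one <- random_table(7, 12, 1)
  red1 <- exhaustive_reduct(one, 0.25, 0.3)
  expect_equal(red1$selected, 1L)
  expect_equal(red1$risk, red1$risk_C)

  # consistent 2-attribute table with one redundant attribute: the singleton
  # informative subset wins
  x_sep <- c(seq(0, 0.05, length.out = 6), seq(0.9, 0.95, length.out = 6))
  tbl <- decision_table(cbind(x_sep, rep(0.5, 12)),
                        factor(rep(c("u", "v"), each = 6)))
  red <- exhaustive_reduct(tbl, 0.25, 0.15)
  expect_equal(red$selected, 1L)

  expect_error(exhaustive_reduct(random_table(3, 10, 11), 0.25, 0.15),
               class = "roughpnn_error_value")
})

test_that("reduct JSON serialization carries the documented fields", {
  red <- reduce_attributes(random_table(55, 20, 4), xi = 0.25, delta = 0.3)
  p <- withr::local_tempfile(fileext = ".json")
  write_reduct_json(red, p)
  obj <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_setequal(names(obj),
                  c("selected", "risk_B", "risk_C", "xi", "delta",
                    "no_reduct", "trace"))
  expect_equal(sort(obj$selected), sort(red$selected))
  expect_equal(obj$risk_B, red$risk)
})
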