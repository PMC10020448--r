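# label vectors reproducing the canonical train/test outcomes of the
# 400/169 diagnostic split: 3 malignant predicted benign in training;
# 1 benign and 4 malignant errors in testing (benign is positive)
train_outcome <- function() {
  truth <- c(rep("benign", 250), rep("malignant", 150))
  pred <- truth
  pred[251:253] <- "benign"
  list(truth = truth, pred = pred)
}
test_outcome <- function() {
  truth <- c(rep("benign", 107), rep("malignant", 62))
  pred <- truth
  pred[1] <- "malignant"
  pred[108:111] <- "benign"
  list(truth = truth, pred = pred)
}

test_that("confusion counts are exact for the canonical outcomes", {
  o <- train_outcome()
  cc <- confusion_counts(o$truth, o$pred, positive = "benign")
  expect_equal(cc[c("tp", "fp", "fn", "tn")],
               tibble::tibble(tp = 250L, fp = 3L, fn = 0L, tn = 147L))

  o2 <- test_outcome()
  cc2 <- confusion_counts(o2$truth, o2$pred, positive = "benign")
  expect_equal(cc2[c("tp", "fp", "fn", "tn")],
               tibble::tibble(tp = 106L, fp = 4L, fn = 1L, tn = 58L))

  all_right <- confusion_counts(o$truth, o$truth, "benign")
  expect_equal(all_right$fp + all_right$fn, 0L)

  expect_error(confusion_counts(c("a", "b"), "a", "a"),
               class = "roughpnn_error_value")
})

test_that("metrics are the exact count ratios, undefined reported as NA", {
  o <- train_outcome()
  m <- classification_metrics(confusion_counts(o$truth, o$pred, "benign"))
  expect_equal(m$accuracy, 397 / 400)
  expect_equal(m$precision, 250 / 253)
  expect_equal(m$recall, 250 / 250)

  o2 <- test_outcome()
  m2 <- classification_metrics(confusion_counts(o2$truth, o2$pred, "benign"))
  expect_equal(m2$accuracy, 164 / 169)
  expect_equal(m2$precision, 106 / 110)
  expect_equal(m2$recall, 106 / 107)

  # nothing predicted positive: precision undefined, not zero
  m3 <- classification_metrics(tibble::tibble(tp = 0L, fp = 0L, fn = 2L,
                                              tn = 8L, n = 10L))
  expect_true(is.na(m3$precision))
  expect_equal(m3$recall, 0)
})

test_that("metrics from counts equal sample-wise computation", {
  for (seed in 40:43) {
    set.seed(seed)
    truth <- sample(c("p", "q"), 60, replace = TRUE)
    pred <- ifelse(runif(60) < 0.3, sample(c("p", "q"), 60, TRUE), truth)
    m <- classification_metrics(confusion_counts(truth, pred, "p"))
    expect_equal(m$accuracy, mean(truth == pred))
    expect_equal(m$recall, mean(pred[truth == "p"] == "p"))
    if (any(pred == "p")) {
      expect_equal(m$precision, mean(truth[pred == "p"] == "p"))
    }
  }
})

test_that("Wilson interval matches the independent closed form and bounds", {
  # stats::prop.test without continuity correction is an independent Wilson
  # implementation
  for (case in list(c(397, 400), c(164, 169), c(7, 10), c(1, 2))) {
    ci <- proportion_ci(case[1], case[2], 0.95)
    ref <- suppressWarnings(prop.test(case[1], case[2], correct = FALSE))$conf.int
    expect_equal(ci$low, ref[1], tolerance = 1e-10)
    expect_equal(ci$high, ref[2], tolerance = 1e-10)
  }
  expect_equal(proportion_ci(25, 25)$high, 1)
  expect_equal(proportion_ci(0, 25)$low, 0)
  # width shrinks with n at fixed proportion
  widths <- vapply(c(20, 80, 320, 1280), function(n) {
    ci <- proportion_ci(round(0.9 * n), n)
    ci$high - ci$low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_error(proportion_ci(5, 4), class = "roughpnn_error_value")
})

test_that("confusion report bundles counts, metrics and interval coherently", {
  o <- train_outcome()
  rep <- confusion_report(o$truth, o$pred, "benign")
  expect_equal(rep$tp + rep$fp + rep$fn + rep$tn, rep$n)
  expect_lte(rep$ci_low, rep$accuracy)
  expect_gte(rep$ci_high, rep$accuracy)
  g <- glance(rep)
  expect_equal(g$accuracy, 397 / 400)
  expect_equal(sum(tidy(rep)$count), 400L)
})

small_synth <- function(seed = 5) {
  generate_table(synthetic_spec(
    n_per_class = c(benign = 60, malignant = 40), k_informative = 3,
    k_redundant = 1, k_noise = 2, class_separation = 3, seed = seed))
}

test_that("compensation-coefficient sweep covers the grid deterministically", {
  tbl <- small_synth()
  counts <- c(benign = 40, malignant = 26)
  sw <- sweep_xi(tbl, train_counts = counts, seed = 3)
  expect_equal(nrow(sw), 8L) # 0.05 .. 0.40 by 0.05
  expect_equal(sw$xi, seq(0.05, 0.40, by = 0.05))
  expect_true(all(sw$dim >= 1))
  expect_true(all(sw$train_acc >= 0 & sw$train_acc <= 1))

  sw1 <- sweep_xi(tbl, xi_grid = 0.25, train_counts = counts, seed = 3)
  expect_equal(nrow(sw1), 1L)

  sw2 <- sweep_xi(tbl, train_counts = counts, seed = 3)
  expect_equal(sw[setdiff(names(sw), "elapsed_s")],
               sw2[setdiff(names(sw2), "elapsed_s")])

  expect_error(sweep_xi(tbl, xi_grid = numeric(0), train_counts = counts),
               class = "roughpnn_error_value")
})

test_that("spread sweep matches direct fits at each grid point", {
  tbl <- small_synth(6)
  sp <- stratified_split(tbl, c(benign = 40, malignant = 26), seed = 2)
  sw <- sweep_spread(sp$train, sp$test)
  expect_equal(nrow(sw), 22L) # 0.50 .. 1.55 by 0.05
  expect_equal(sw$sigma[1], 0.5)
  expect_equal(sw$sigma[22], 1.55)

  one <- sweep_spread(sp$train, sp$test, spread_grid = 0.75)
  expect_equal(nrow(one), 1L)
  # independent re-run outside the sweep machinery
  st <- fit_scaling(sp$train, method = "zscore")
  tr <- apply_scaling(st, sp$train)
  te <- apply_scaling(st, sp$test)
  model <- pnn(tr, sigma = 0.75)
  expect_equal(one$train_acc, mean(predict(model, tr) == tr$label))
  expect_equal(one$test_acc, mean(predict(model, te) == te$label))

  p <- withr::local_tempfile(fileext = ".csv")
  write_sweep_csv(sw, p)
  expect_equal(nrow(utils::read.csv(p)), 22L)
})
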