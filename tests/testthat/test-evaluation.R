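mk_result <- function(left_id = character(0), right_id = character(0),
                      step = integer(0), score = numeric(0)) {
  m <- data.table::data.table(left_id = left_id, right_id = right_id,
                              step = step, score = score)
  structure(list(matches = m, per_step_counts = table(m$step),
                 unmatched_left = character(0)), class = "linkage_result")
}

left_with_truth <- function(ids, truth) {
  data.table::data.table(record_id = ids, full_name = "X", mother_name = "Y",
                         birth_date = as.Date("1950-01-01"), truth_ref = truth)
}

test_that("confusion matrix classifies per left record, wrong links doubly", {
  left <- left_with_truth(c("P1", "P2", "N1", "N2"),
                          c("R1", "R2", NA, NA))
  res <- mk_result(c("P1", "P2"), c("R1", "R2"), c(1L, 1L), c(1, 1))
  cm <- confusion_from_links(res, left)
  expect_equal(unlist(cm), c(tp = 2L, fp = 0L, tn = 2L, fn = 0L))

  # one positive linked to the wrong right record: both FP and FN
  left2 <- left_with_truth(c("P1", "N1"), c("R1", NA))
  res2 <- mk_result("P1", "R9", 3L, 0.97)
  expect_equal(unlist(confusion_from_links(res2, left2)),
               c(tp = 0L, fp = 1L, tn = 1L, fn = 1L))

  # empty result over negatives only
  left3 <- left_with_truth(c("N1", "N2", "N3"), rep(NA_character_, 3))
  expect_equal(unlist(confusion_from_links(mk_result(), left3)),
               c(tp = 0L, fp = 0L, tn = 3L, fn = 0L))

  # matched negative is a false positive
  res4 <- mk_result("N1", "R5", 13L, 0.96)
  expect_equal(unlist(confusion_from_links(res4, left3)),
               c(tp = 0L, fp = 1L, tn = 2L, fn = 0L))

  no_truth <- left3[, .(record_id, full_name, mother_name, birth_date)]
  expect_error(confusion_from_links(mk_result(), no_truth),
               class = "hierlink_validation_error")
})

test_that("binomial intervals reproduce published diagnostic intervals", {
  # sensitivity row, low-prevalence scenario: 10830/11500 -> [0.937; 0.946]
  expect_equal(round_half_up(binomial_ci(10830, 11500), 3), c(0.937, 0.946))
  # NPV row: 218473/219143 -> [0.997; 0.997]
  expect_equal(round_half_up(binomial_ci(218473, 219143), 3), c(0.997, 0.997))
  # degenerate Wald at p = 1, clamped
  expect_equal(binomial_ci(100, 100), c(1, 1))
  expect_error(binomial_ci(1, 0), class = "hierlink_validation_error")

  # alternative interval methods stay inside [0,1] and contain the estimate
  for (meth in c("wald", "wilson", "clopper-pearson")) {
    ci <- binomial_ci(3, 10, method = meth)
    expect_true(ci[1] >= 0 && ci[2] <= 1 && ci[1] <= 0.3 && ci[2] >= 0.3)
  }
  # Wilson and exact intervals never degenerate at the boundary
  expect_gt(binomial_ci(10, 10, method = "wilson")[1], 0.6)
  expect_lt(binomial_ci(0, 10, method = "clopper-pearson")[2], 0.5)
})

test_that("accuracy reports reproduce the published confusion-count arithmetic", {
  # low-prevalence scenario counts
  r5 <- accuracy_report(confusion_matrix(tp = 10830, fp = 27, tn = 218473, fn = 670))
  est <- function(r, m) round_half_up(r$estimate[r$metric == m], 3)
  expect_equal(est(r5, "sensitivity"), 0.942)
  expect_equal(est(r5, "ppv"), 0.998)
  expect_equal(est(r5, "npv"), 0.997)
  expect_equal(est(r5, "accuracy"), 0.997)

  # high-prevalence scenario counts
  r50 <- accuracy_report(confusion_matrix(tp = 10777, fp = 0, tn = 11500, fn = 723))
  expect_equal(est(r50, "ppv"), 1.000)
  expect_equal(est(r50, "npv"), 0.941)
  expect_equal(est(r50, "accuracy"), 0.969)

  perfect <- accuracy_report(confusion_matrix(1, 0, 1, 0))
  expect_true(all(perfect$estimate == 1))
})

test_that("report metrics are bounded, CI-covered, and accuracy is the weighted mean", {
  set.seed(9)
  for (i in 1:20) {
    cts <- sample(0:50, 4, replace = TRUE)
    cm <- confusion_matrix(cts[1], cts[2], cts[3], cts[4])
    r <- accuracy_report(cm)
    ok <- !is.na(r$estimate)
    expect_true(all(r$estimate[ok] >= 0 & r$estimate[ok] <= 1))
    expect_true(all(r$lower[ok] <= r$estimate[ok] + 1e-12))
    expect_true(all(r$upper[ok] >= r$estimate[ok] - 1e-12))
    sens <- r$estimate[r$metric == "sensitivity"]
    spec <- r$estimate[r$metric == "specificity"]
    acc <- r$estimate[r$metric == "accuracy"]
    if (!is.na(sens) && !is.na(spec)) {
      npos <- cm$tp + cm$fn; nneg <- cm$tn + cm$fp
      expect_equal(acc, (sens * npos + spec * nneg) / (npos + nneg), tolerance = 1e-12)
    }
  }
  # zero denominator reports NA, not zero
  r0 <- accuracy_report(confusion_matrix(0, 0, 5, 0))
  expect_true(is.na(r0$estimate[r0$metric == "sensitivity"]))
  expect_true(is.na(r0$estimate[r0$metric == "ppv"]))
})

test_that("report files mirror the metric table shape", {
  r <- accuracy_report(confusion_matrix(10, 1, 80, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(list(pad05 = r, pad50 = r), path)
  tab <- data.table::fread(path)
  expect_equal(nrow(tab), 10L)
  expect_true(all(c("scenario", "metric", "estimate", "lower", "upper") %in% names(tab)))
  expect_setequal(unique(tab$scenario), c("pad05", "pad50"))
})
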