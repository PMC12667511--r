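#' Build a confusion matrix from a linkage result and ground truth
#'
#' Each left record carries a `truth_ref`: the id of its true counterpart in
#' the right registry, or `NA` when it has none. Classification is per left
#' record: a true positive is a link to exactly the right counterpart; an
#' unlinked positive is a false negative; a positive linked to the wrong
#' right record counts both as a false positive and a false negative (the
#' true counterpart was missed *and* a wrong pair was asserted); a linked
#' negative is a false positive and an unlinked negative a true negative.
#'
#' @param result a `linkage_result` from [run_linkage()].
#' @param left the left registry (raw or normalized) including a `truth_ref`
#'   column (`NA` = no counterpart).
#' @return an object of class `confusion_matrix`: list with integer fields
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_from_links <- function(result, left) {
  if (!inherits(result, "linkage_result")) stop_config("result must be a linkage_result")
  left <- data.table::as.data.table(left)
  if (!"truth_ref" %in% names(left)) {
    stop_validation("left registry lacks a truth_ref column; ground truth is required")
  }
  truth <- as.character(left$truth_ref)
  truth[!is.na(truth) & !nzchar(truth)] <- NA_character_
  ids <- as.character(left$record_id)
  linked <- stats::setNames(result$matches$right_id, result$matches$left_id)
  got <- linked[ids]

  pos <- !is.na(truth)
  tp <- sum(pos & !is.na(got) & got == truth)
  wrong <- sum(pos & !is.na(got) & got != truth)
  fn <- sum(pos & is.na(got)) + wrong
  fp <- sum(!pos & !is.na(got)) + wrong
  tn <- sum(!pos & is.na(got))
  confusion_matrix(tp, fp, tn, fn)
}

#' Construct a confusion matrix
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return an object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(is.na(v)) || any(v < 0)) stop_config("confusion counts must be non-negative")
  v <- stats::setNames(as.integer(round(v)), names(v))
  structure(as.list(v), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix: TP=%d FP=%d TN=%d FN=%d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Binomial confidence interval for a proportion
#'
#' Default is the Wald interval `p +/- z * sqrt(p(1-p)/n)` clamped to
#' \[0, 1\]; Wilson (score) and Clopper-Pearson (exact) intervals are
#' available since reported intervals in the diagnostic-accuracy literature
#' vary in method.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (> 0).
#' @param level confidence level, default 0.95.
#' @param method `"wald"`, `"wilson"` or `"clopper-pearson"`.
#' @return numeric vector `c(lower, upper)`.
#' @export
binomial_ci <- function(k, n, level = 0.95,
                        method = c("wald", "wilson", "clopper-pearson")) {
  method <- match.arg(method)
  if (n <= 0) stop_validation("binomial_ci is undefined for n = 0")
  if (k < 0 || k > n) stop_config("k must lie in [0, n]")
  p <- k / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- switch(method,
    wald = {
      half <- z * sqrt(p * (1 - p) / n)
      c(p - half, p + half)
    },
    wilson = {
      den <- 1 + z^2 / n
      ctr <- (p + z^2 / (2 * n)) / den
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
      c(ctr - half, ctr + half)
    },
    `clopper-pearson` = {
      lo <- if (k == 0) 0 else stats::qbeta((1 - level) / 2, k, n - k + 1)
      hi <- if (k == n) 1 else stats::qbeta(1 - (1 - level) / 2, k + 1, n - k)
      c(lo, hi)
    })
  pmin(pmax(ci, 0), 1)
}

#' Diagnostic accuracy report from a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)`, negative predictive value `tn/(tn+fn)` and overall
#' accuracy `(tp+tn)/total`, each with a binomial confidence interval over
#' its own denominator. A metric with zero denominator is reported as `NA`
#' (undefined), never as 0.
#'
#' @param cm a [confusion_matrix()].
#' @param level confidence level.
#' @param ci_method interval method, see [binomial_ci()].
#' @return an object of class `accuracy_report`: `data.frame` with columns
#'   `metric`, `estimate`, `lower`, `upper`; the confusion counts and CI
#'   method are kept as attributes.
#' @export
accuracy_report <- function(cm, level = 0.95, ci_method = "wald") {
  if (!inherits(cm, "confusion_matrix")) stop_config("cm must be a confusion_matrix")
  num <- c(sensitivity = cm$tp, specificity = cm$tn, ppv = cm$tp,
           npv = cm$tn, accuracy = cm$tp + cm$tn)
  den <- c(sensitivity = cm$tp + cm$fn, specificity = cm$tn + cm$fp,
           ppv = cm$tp + cm$fp, npv = cm$tn + cm$fn,
           accuracy = cm$tp + cm$fp + cm$tn + cm$fn)
  rows <- lapply(names(num), function(m) {
    if (den[[m]] == 0) {
      data.frame(metric = m, estimate = NA_real_, lower = NA_real_, upper = NA_real_)
    } else {
      ci <- binomial_ci(num[[m]], den[[m]], level, ci_method)
      data.frame(metric = m, estimate = num[[m]] / den[[m]],
                 lower = ci[1], upper = ci[2])
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "counts") <- unlist(cm)
  attr(out, "level") <- level
  attr(out, "ci_method") <- ci_method
  class(out) <- c("accuracy_report", "data.frame")
  out
}

#' @export
print.accuracy_report <- function(x, digits = 3, ...) {
  cts <- attr(x, "counts")
  cat(sprintf("Accuracy report (TP=%d FP=%d TN=%d FN=%d, %s %g%% CI)\n",
              cts["tp"], cts["fp"], cts["tn"], cts["fn"],
              attr(x, "ci_method"), 100 * attr(x, "level")))
  for (i in seq_len(nrow(x))) {
    if (is.na(x$estimate[i])) {
      cat(sprintf("  %-12s undefined\n", x$metric[i]))
    } else {
      cat(sprintf("  %-12s %.3f [%.3f; %.3f]\n", x$metric[i],
                  round_half_up(x$estimate[i], digits),
                  round_half_up(x$lower[i], digits),
                  round_half_up(x$upper[i], digits)))
    }
  }
  invisible(x)
}

#' Write accuracy reports to a delimited file
#'
#' One row per metric; an optional `scenario` label column distinguishes
#' reports from several benchmark scenarios in one file.
#'
#' @param reports a single `accuracy_report` or a named list of them
#'   (names become the `scenario` column).
#' @param path output path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_report <- function(reports, path, delim = ",") {
  if (inherits(reports, "accuracy_report")) reports <- list(overall = reports)
  rows <- data.table::rbindlist(lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    cts <- attr(r, "counts")
    data.table::data.table(scenario = nm, metric = r$metric,
                           estimate = r$estimate, lower = r$lower,
                           upper = r$upper,
                           tp = cts["tp"], fp = cts["fp"],
                           tn = cts["tn"], fn = cts["fn"])
  }))
  data.table::fwrite(rows, path, sep = delim, quote = FALSE)
  invisible(path)
}
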