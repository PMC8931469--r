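# Evaluation framework: tolerance-window confusion matrices ("threshold
# method"), signed days-difference summaries, exact binomial confidence
# intervals, ovulation-timing classes, and nonparametric group comparisons.
#
# Every cycle is one independent statistical unit; a test method's call is
# scored against a reference ("gold standard") call for the same cycle.

#' Classify one cycle against the reference
#'
#' Both positive with the test day within `tolerance_days` of the reference
#' day: TP. Test positive otherwise (outside the window, or the reference
#' negative): FP. Both negative: TN. Test negative but reference positive:
#' FN.
#'
#' @param test,ref [ovulation_call()] objects for the same cycle.
#' @param tolerance_days Agreement window in days (1 and 3 are the
#'   conventional choices: day-of-ovulation and fertile-window agreement).
#' @return One of `"TP"`, `"FP"`, `"TN"`, `"FN"`.
#' @export
classify_cycle <- function(test, ref, tolerance_days) {
  if (is_positive(test)) {
    if (is_positive(ref) &&
        abs(test$ovulation_day - ref$ovulation_day) <= tolerance_days) "TP"
    else "FP"
  } else {
    if (is_positive(ref)) "FN" else "TN"
  }
}

#' Aggregate per-cycle classifications to confusion counts
#'
#' @param test_calls,ref_calls Parallel lists of [ovulation_call()] objects,
#'   one element per cycle.
#' @param tolerance_days Agreement window in days.
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`, `tolerance_days`; the four counts sum to the number of
#'   cycles.
#' @export
confusion_counts <- function(test_calls, ref_calls, tolerance_days) {
  stopifnot(length(test_calls) == length(ref_calls))
  cls <- mapply(classify_cycle, test_calls, ref_calls,
                MoreArgs = list(tolerance_days = tolerance_days))
  counts <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  if (length(cls)) {
    tab <- table(factor(cls, levels = names(counts)))
    counts[] <- as.integer(tab)
  }
  new_confusion_counts(counts[["TP"]], counts[["FP"]], counts[["TN"]],
                       counts[["FN"]], tolerance_days)
}

#' Construct confusion counts directly
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @param tolerance_days Agreement window the counts were scored at.
#' @return An object of class `confusion_counts`.
#' @export
new_confusion_counts <- function(tp, fp, tn, fn, tolerance_days = 3L) {
  counts <- as.integer(c(tp, fp, tn, fn))
  if (anyNA(counts) || any(counts < 0L))
    domain_error("confusion counts must be non-negative integers")
  structure(list(tp = counts[1], fp = counts[2], tn = counts[3],
                 fn = counts[4], tolerance_days = as.integer(tolerance_days)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion (+/-%d days): TP %d, FP %d, TN %d, FN %d>\n",
              x$tolerance_days, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Beta-quantile interval for a binomial proportion. With
#' `allow_noninteger = TRUE` the same Beta-shape formula is applied with
#' continuous (e.g. half-integer) successes/trials, as needed for the
#' F-score proportion TP / (TP + (FP + FN) / 2).
#'
#' @param successes,trials Counts, `0 <= successes <= trials`, `trials > 0`.
#' @param level Confidence level (default 0.95).
#' @param allow_noninteger Permit non-integer successes/trials.
#' @return Numeric vector `c(lower, upper)`. The lower bound is exactly 0
#'   when `successes == 0` and the upper exactly 1 when
#'   `successes == trials`.
#' @export
clopper_pearson <- function(successes, trials, level = 0.95,
                            allow_noninteger = FALSE) {
  if (trials <= 0) domain_error("trials must be > 0")
  if (successes < 0 || successes > trials)
    domain_error("successes must lie in [0, trials]")
  if (!allow_noninteger &&
      (successes != round(successes) || trials != round(trials)))
    domain_error("non-integer counts require allow_noninteger = TRUE")
  a <- 1 - level
  lower <- if (successes <= 0) 0 else
    stats::qbeta(a / 2, successes, trials - successes + 1)
  upper <- if (successes >= trials) 1 else
    stats::qbeta(1 - a / 2, successes + 1, trials - successes)
  c(lower = lower, upper = upper)
}

#' Wilson score interval
#'
#' Available as an alternative interval for binomial proportions.
#'
#' @inheritParams clopper_pearson
#' @return Numeric vector `c(lower, upper)`.
#' @export
wilson_interval <- function(successes, trials, level = 0.95) {
  if (trials <= 0) domain_error("trials must be > 0")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  centre <- (p + z^2 / (2 * trials)) / denom
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Diagnostic metrics with confidence intervals
#'
#' Standard forms: sensitivity TP/(TP+FN), specificity TN/(TN+FP),
#' PPV TP/(TP+FP), NPV TN/(TN+FN), accuracy (TP+TN)/total, and
#' F score TP/(TP + (FP+FN)/2). A metric whose denominator is zero is
#' reported as `NA` (absent), not 0. Confidence intervals are exact binomial
#' by default; the F-score interval uses the generalized (continuous Beta
#' shape) form on its possibly half-integer denominator.
#'
#' @param counts A `confusion_counts` object.
#' @param level Confidence level (default 0.95).
#' @param ci_method `"clopper-pearson"` (default) or `"wilson"`.
#' @return A data frame of class `metric_set` with columns `metric`,
#'   `value`, `lower`, `upper`, `successes`, `trials`.
#' @export
compute_metrics <- function(counts, level = 0.95,
                            ci_method = c("clopper-pearson", "wilson")) {
  stopifnot(inherits(counts, "confusion_counts"))
  ci_method <- match.arg(ci_method)
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  defs <- list(
    sensitivity = c(tp, tp + fn),
    specificity = c(tn, tn + fp),
    ppv         = c(tp, tp + fp),
    npv         = c(tn, tn + fn),
    accuracy    = c(tp + tn, tp + fp + tn + fn),
    f_score     = c(tp, tp + (fp + fn) / 2))
  rows <- lapply(names(defs), function(nm) {
    s <- defs[[nm]][1]; n <- defs[[nm]][2]
    if (n <= 0)
      return(data.frame(metric = nm, value = NA_real_, lower = NA_real_,
                        upper = NA_real_, successes = s, trials = n))
    ci <- if (ci_method == "clopper-pearson")
      clopper_pearson(s, n, level, allow_noninteger = TRUE)
    else wilson_interval(s, n, level)
    data.frame(metric = nm, value = s / n, lower = ci[[1]], upper = ci[[2]],
               successes = s, trials = n)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("metric_set", "data.frame")
  attr(out, "tolerance_days") <- counts$tolerance_days
  out
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("Diagnostic metrics (+/-%s days tolerance):\n",
              attr(x, "tolerance_days") %||% "?"))
  for (i in seq_len(nrow(x))) {
    v <- x$value[i]
    shown <- if (is.na(v)) "--"
    else if (x$metric[i] == "f_score") sprintf("%.2f [%.2f, %.2f]", v, x$lower[i], x$upper[i])
    else if (x$metric[i] == "accuracy") sprintf("%.1f%% [%.1f%%, %.1f%%]",
                                                100 * v, 100 * x$lower[i], 100 * x$upper[i])
    else sprintf("%.0f%%", 100 * v)
    cat(sprintf("  %-12s %s\n", x$metric[i], shown))
  }
  invisible(x)
}

#' Report-style rounding of a metric set
#'
#' Rounds the raw proportions the way comparative reports print them:
#' rates (sensitivity, specificity, PPV, NPV) to whole percent, accuracy to
#' one decimal percent, F score to two decimals. Full-precision values stay
#' in the `metric_set` itself.
#'
#' Rounding is half-up (1.25 -> 1.3), the convention of such reports, rather
#' than R's round-half-even.
#'
#' @param metrics A `metric_set` from [compute_metrics()].
#' @return Named numeric vector of rounded display values.
#' @export
round_metrics_for_report <- function(metrics) {
  get <- function(nm) metrics$value[metrics$metric == nm]
  c(sensitivity_pct = round_half_up(100 * get("sensitivity")),
    specificity_pct = round_half_up(100 * get("specificity")),
    ppv_pct = round_half_up(100 * get("ppv")),
    npv_pct = round_half_up(100 * get("npv")),
    accuracy_pct = round_half_up(100 * get("accuracy"), 1),
    f_score = round_half_up(get("f_score"), 2))
}

round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5 + 1e-9) / s
}

#' Days-difference summary (test minus reference)
#'
#' Restricted to cycles where both methods confirmed ovulation. Negative
#' means the test method confirms earlier in the cycle than the reference.
#' The interval is the normal approximation mean +/- z * SD / sqrt(n); the
#' SD uses the n-1 denominator. With a single pair the SD and interval are
#' reported as `NA`.
#'
#' @param test_days,ref_days Parallel numeric vectors of confirmed days.
#' @param level Confidence level (default 0.95).
#' @return An object of class `days_difference_summary` with fields `n`,
#'   `mean_diff`, `sd_diff`, `ci_low`, `ci_high`; `NULL` when no pairs.
#' @export
days_difference_summary <- function(test_days, ref_days = 0, level = 0.95) {
  d <- as.numeric(test_days) - as.numeric(ref_days)
  d <- d[!is.na(d)]
  n <- length(d)
  if (n == 0L) return(NULL)
  m <- mean(d)
  s <- if (n > 1L) stats::sd(d) else NA_real_
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- if (n > 1L) z * s / sqrt(n) else NA_real_
  structure(list(n = n, mean_diff = m, sd_diff = s,
                 ci_low = m - half, ci_high = m + half),
            class = "days_difference_summary")
}

#' @export
print.days_difference_summary <- function(x, ...) {
  cat(sprintf("<days difference: n=%d, mean %.2f, SD %s, 95%% CI [%.2f, %.2f]>\n",
              x$n, x$mean_diff,
              ifelse(is.na(x$sd_diff), "--", sprintf("%.2f", x$sd_diff)),
              x$ci_low, x$ci_high))
  invisible(x)
}

#' Ovulation-timing class
#'
#' Classifies a confirmed ovulation by its position in the cycle:
#' `"late"` when the ovulation day is strictly more than 65% of the way
#' through the cycle, `"early"` when strictly less than 40%, else
#' `"normal"`. Fractions of exactly 0.40 or 0.65 are `"normal"`.
#'
#' @param ovulation_day Confirmed ovulation day.
#' @param cycle_length Cycle length in days; must be `>= ovulation_day`.
#' @return A list with `label` and `fraction`.
#' @export
timing_class <- function(ovulation_day, cycle_length) {
  if (ovulation_day < 1 || ovulation_day > cycle_length)
    domain_error("ovulation_day must lie in [1, cycle_length]")
  frac <- ovulation_day / cycle_length
  eps <- 1e-12
  label <- if (frac > 0.65 + eps) "late"
  else if (frac < 0.40 - eps) "early"
  else "normal"
  list(label = label, fraction = frac)
}

#' Classify one prediction against the subsequent cycle's reference result
#'
#' Predicting a negative has no meaning, so cycles whose reference result is
#' negative are excluded and TN is identically zero; downstream accuracy is
#' TP / (TP + FP + FN). An unavailable prediction (no ovulatory history)
#' while the reference method could predict is an FN.
#'
#' @param pred A `predicted_ovulation` from [predict_next_ovulation()].
#' @param actual_ref The reference [ovulation_call()] for the subsequent
#'   cycle.
#' @param tolerance_days Agreement window in days.
#' @param reference_available Could the reference method itself produce a
#'   prediction for this cycle? When `FALSE`, an unavailable test prediction
#'   is excluded rather than counted FN.
#' @return One of `"TP"`, `"FP"`, `"FN"`, `"excluded"`.
#' @export
prediction_confusion <- function(pred, actual_ref, tolerance_days,
                                 reference_available = TRUE) {
  if (!is_positive(actual_ref)) return("excluded")
  if (pred$status == "predicted") {
    if (abs(pred$day - actual_ref$ovulation_day) <= tolerance_days) "TP" else "FP"
  } else {
    if (isTRUE(reference_available)) "FN" else "excluded"
  }
}

#' Mann-Whitney rank-sum comparison of two samples
#'
#' Delegates to [stats::wilcox.test()]; the statistic is U for the first
#' sample (the number of (a, b) pairs with a ahead of b in rank), with the
#' two-sided p-value. Tie correction is applied by the normal approximation
#' when ties are present.
#'
#' @param a,b Non-empty numeric samples.
#' @return A list with `statistic`, `p_value`, `test = "mann_whitney"`.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) domain_error("samples must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       test = "mann_whitney")
}

#' Kruskal-Wallis rank comparison of several samples
#'
#' Delegates to [stats::kruskal.test()].
#'
#' @param samples List of non-empty numeric samples.
#' @return A list with `statistic` (H), `p_value`, `test = "kruskal_wallis"`.
#' @export
kruskal_wallis <- function(samples) {
  if (!length(samples) || any(!lengths(samples)))
    domain_error("all samples must be non-empty")
  kt <- stats::kruskal.test(samples)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       test = "kruskal_wallis")
}
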