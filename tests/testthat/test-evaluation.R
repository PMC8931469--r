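test_that("per-cycle classification implements the tolerance-window rules", {
  expect_equal(classify_cycle(pos_call(15), pos_call(17), 3), "TP")
  expect_equal(classify_cycle(pos_call(15), pos_call(17), 1), "FP")
  expect_equal(classify_cycle(neg_call(), neg_call(), 3), "TN")
  expect_equal(classify_cycle(neg_call(), pos_call(17), 3), "FN")
  expect_equal(classify_cycle(pos_call(15), neg_call(), 3), "FP")
  # boundary: exactly at the tolerance counts as agreement
  expect_equal(classify_cycle(pos_call(14), pos_call(17), 3), "TP")
})

test_that("confusion counts sum to the number of scored cycles", {
  test <- list(pos_call(15), pos_call(15), neg_call(), neg_call())
  ref  <- list(pos_call(17), neg_call(), neg_call(), pos_call(17))
  cc <- confusion_counts(test, ref, 3)
  expect_equal(cc$tp, 1L); expect_equal(cc$fp, 1L)
  expect_equal(cc$tn, 1L); expect_equal(cc$fn, 1L)
  empty <- confusion_counts(list(), list(), 3)
  expect_equal(empty$tp + empty$fp + empty$tn + empty$fn, 0L)
  set.seed(12)
  pop <- generate_population(simulation_params(n_participants = 30,
                                               cycles_per_participant = 2,
                                               seed = 12))
  calls <- detect_pairs(pop)
  cc2 <- confusion_counts(calls_from_status(calls$test_status, calls$test_day),
                          calls_from_status(calls$ref_status, calls$ref_day), 3)
  expect_equal(cc2$tp + cc2$fp + cc2$tn + cc2$fn, length(pop))
})

test_that("TP/FP move with tolerance but TN/FN do not", {
  set.seed(77)
  test <- ref <- list()
  for (i in 1:120) {
    test[[i]] <- if (runif(1) < 0.8) pos_call(sample(10:24, 1)) else neg_call()
    ref[[i]]  <- if (runif(1) < 0.8) pos_call(sample(10:24, 1)) else neg_call()
  }
  c1 <- confusion_counts(test, ref, 1)
  c3 <- confusion_counts(test, ref, 3)
  expect_gte(c3$tp, c1$tp)
  expect_lte(c3$fp, c1$fp)
  expect_equal(c3$tn, c1$tn)
  expect_equal(c3$fn, c1$fn)
})

test_that("metric formulas reproduce the study's printed headline cells", {
  # combined set, +/-3 days, skin-worn method
  m <- compute_metrics(new_confusion_counts(140, 11, 45, 9, 3))
  g <- function(nm) m$value[m$metric == nm]
  expect_equal(round(g("accuracy"), 3), 0.902)
  expect_equal(round(g("f_score"), 2), 0.93)
  expect_equal(round(g("sensitivity"), 2), 0.94)
  expect_equal(round(g("specificity"), 2), 0.80)
  expect_equal(round(g("ppv"), 2), 0.93)
  expect_equal(round(g("npv"), 2), 0.83)
  # wrist subgroup, +/-3 days
  m2 <- compute_metrics(new_confusion_counts(37, 1, 11, 2, 3))
  expect_equal(round(m2$value[m2$metric == "accuracy"], 3), 0.941)
  expect_equal(round(m2$value[m2$metric == "f_score"], 3), 0.961)
})

test_that("zero-denominator metrics are absent, not zero", {
  m <- compute_metrics(new_confusion_counts(0, 0, 5, 0, 3))
  expect_equal(m$value[m$metric == "accuracy"], 1.0)
  expect_true(is.na(m$value[m$metric == "sensitivity"]))
  expect_true(is.na(m$value[m$metric == "ppv"]))
  expect_true(is.na(m$value[m$metric == "f_score"]))
  expect_equal(m$value[m$metric == "specificity"], 1.0)
})

test_that("every metric lies inside its own confidence interval", {
  set.seed(5)
  for (i in 1:25) {
    cc <- new_confusion_counts(sample(0:50, 1), sample(0:20, 1),
                               sample(0:30, 1), sample(0:20, 1), 3)
    if (cc$tp + cc$fp + cc$tn + cc$fn == 0) next
    m <- compute_metrics(cc)
    ok <- !is.na(m$value)
    expect_true(all(m$lower[ok] - 1e-12 <= m$value[ok]))
    expect_true(all(m$value[ok] <= m$upper[ok] + 1e-12))
    expect_true(all(m$lower[ok] >= 0) && all(m$upper[ok] <= 1))
  }
})

test_that("exact binomial interval hits boundaries and shrinks with n", {
  expect_equal(clopper_pearson(0, 10)[["lower"]], 0)
  expect_equal(clopper_pearson(10, 10)[["upper"]], 1)
  w1 <- diff(clopper_pearson(20, 40))
  w2 <- diff(clopper_pearson(40, 80))
  w3 <- diff(clopper_pearson(80, 160))
  expect_true(w2 < w1 && w3 < w2)
  expect_error(clopper_pearson(11, 10), class = "ovutherm_domain_error")
  expect_error(clopper_pearson(3.5, 10), class = "ovutherm_domain_error")
  # half-integer counts allowed for the F-score proportion
  ci <- clopper_pearson(37, 38.5, allow_noninteger = TRUE)
  expect_true(ci[["lower"]] > 0 && ci[["upper"]] < 1)
  # agrees with binom.test on integer counts
  bt <- binom.test(51, 85)$conf.int
  ci2 <- clopper_pearson(51, 85)
  expect_equal(unname(ci2), as.numeric(bt), tolerance = 1e-10)
})

test_that("wilson interval is a valid alternative", {
  ci <- wilson_interval(51, 85)
  expect_true(ci[["lower"]] < 51 / 85 && 51 / 85 < ci[["upper"]])
  m <- compute_metrics(new_confusion_counts(140, 11, 45, 9, 3),
                       ci_method = "wilson")
  expect_true(all(!is.na(m$lower)))
})

test_that("days-difference summary matches hand arithmetic", {
  s <- days_difference_summary(c(-2, -1, 0))
  expect_equal(s$n, 3L)
  expect_equal(s$mean_diff, -1.0)
  expect_equal(s$sd_diff, 1.0)
  z <- qnorm(0.975)
  expect_equal(s$ci_low, -1 - z / sqrt(3))
  expect_equal(s$ci_high, -1 + z / sqrt(3))
  # degenerate single pair: SD and interval absent by convention
  one <- days_difference_summary(5)
  expect_equal(one$mean_diff, 5)
  expect_true(is.na(one$sd_diff))
  expect_null(days_difference_summary(numeric(0)))
  # signed difference of paired positive days
  s2 <- days_difference_summary(c(14, 15, 16), c(16, 16, 16))
  expect_equal(s2$mean_diff, -1.0)
})

test_that("timing classes use strict thresholds around 40% and 65%", {
  late <- timing_class(20, 30)
  expect_equal(late$label, "late")
  expect_equal(round(100 * late$fraction, 1), 66.7)
  expect_equal(timing_class(12, 30)$label, "normal")   # 0.40 exactly
  expect_equal(timing_class(13, 20)$label, "normal")   # 0.65 exactly
  expect_equal(timing_class(13, 33)$label, "early")    # 0.394
  expect_error(timing_class(31, 30), class = "ovutherm_domain_error")
})

test_that("prediction scoring excludes reference negatives and counts FNs", {
  pred <- function(day) structure(list(status = "predicted", day = day,
                                       n_cycles_used = 3L),
                                  class = "predicted_ovulation")
  unavail <- structure(list(status = "unavailable", day = NA_integer_,
                            n_cycles_used = 0L), class = "predicted_ovulation")
  expect_equal(prediction_confusion(pred(16), pos_call(18), 3), "TP")
  expect_equal(prediction_confusion(pred(16), pos_call(25), 3), "FP")
  expect_equal(prediction_confusion(unavail, pos_call(18), 3), "FN")
  expect_equal(prediction_confusion(unavail, pos_call(18), 3,
                                    reference_available = FALSE), "excluded")
  expect_equal(prediction_confusion(pred(16), neg_call(), 3), "excluded")
  # TN == 0 accuracy equals the general accuracy formula on the same counts
  cc <- new_confusion_counts(54, 31, 0, 0, 3)
  m <- compute_metrics(cc)
  expect_equal(round(100 * m$value[m$metric == "accuracy"], 1), 63.5)
})

test_that("rank tests delegate with documented conventions", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$statistic, 0)  # every a below every b
  expect_true(mw$p_value >= 0 && mw$p_value <= 1)
  same <- mann_whitney(1:10, 1:10)
  expect_gt(same$p_value, 0.9)
  kw <- kruskal_wallis(list(c(1, 5, 9), c(2, 6, 10), c(3, 7, 11)))
  expect_lt(kw$statistic, 1)
  expect_gt(kw$p_value, 0.5)
  expect_error(mann_whitney(numeric(0), 1:3), class = "ovutherm_domain_error")
  expect_error(kruskal_wallis(list(1:3, numeric(0))),
               class = "ovutherm_domain_error")
})

test_that("report rounding follows the half-up convention", {
  m <- compute_metrics(new_confusion_counts(64, 9, 27, 12, 3))
  disp <- round_metrics_for_report(m)
  expect_equal(disp[["accuracy_pct"]], 81.3)  # 91/112 = 81.25 rounds up
  expect_equal(disp[["sensitivity_pct"]], 84)
})
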