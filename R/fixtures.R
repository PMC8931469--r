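# Bundled reference tables: the confusion counts and days-difference
# summaries printed by the comparative skin-vs-vaginal sensor study this
# package models. They serve as standing regression fixtures: recomputing
# the metrics from the counts must reproduce every printed value at its
# printed rounding.

#' Study-reported confusion counts and printed metrics
#'
#' One row per (analysis, grouping, tolerance, method) cell: raw TP/FP/TN/FN
#' together with the summary statistics the study report printed for that
#' cell (rates in whole percent, accuracy in percent to one decimal with its
#' 95% CI, F score to two decimals with its 95% CI). `NA` marks cells the
#' report left blank (e.g. specificity where no true negatives can exist).
#'
#' @return A data frame.
#' @export
study_threshold_counts <- function() {
  utils::read.csv(system.file("extdata", "study_threshold_counts.csv",
                              package = "ovutherm"))
}

#' Study-reported days-difference summaries
#'
#' One row per (analysis, grouping, method): the number of paired positive
#' cycles, the printed mean and SD of the signed days difference
#' (test minus reference), and the printed 95% confidence bounds.
#'
#' @return A data frame.
#' @export
study_days_difference <- function() {
  utils::read.csv(system.file("extdata", "study_days_difference.csv",
                              package = "ovutherm"))
}
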