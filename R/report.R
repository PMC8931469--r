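# Orchestration: configuration handling, simulate -> detect -> predict ->
# evaluate pipelines, and report-table generation. A thin command-line
# wrapper over these functions ships in inst/cli/ovutherm.R.

known_config_keys <- c("seed", "out_dir", "simulation", "detectors",
                       "reference_method", "test_method", "tolerances",
                       "ci_level", "representative")

#' Build and validate a run configuration
#'
#' Accepts a list or a path to a YAML/JSON file. Unknown keys, at the top
#' level or inside the `simulation`/`detectors`/`representative` blocks, are
#' rejected by name. Missing keys take package defaults. Every pipeline
#' command writes its resolved configuration alongside its outputs, so a
#' run is reproducible from that file plus the seed alone.
#'
#' @param x A named list, or a path to a `.yaml`/`.yml`/`.json` file.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(x = list()) {
  if (is.character(x)) {
    x <- if (grepl("\\.json$", x, ignore.case = TRUE)) jsonlite::read_json(x, simplifyVector = TRUE)
    else yaml::read_yaml(x)
    if (is.null(x)) x <- list()
  }
  unknown <- setdiff(names(x), known_config_keys)
  if (length(unknown))
    config_error(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  check_block <- function(block, fn, label) {
    extra <- setdiff(names(block), names(formals(fn)))
    if (length(extra))
      config_error(sprintf("unknown %s key(s): %s", label,
                           paste(extra, collapse = ", ")))
    block
  }
  sim_args <- check_block(x$simulation %||% list(), simulation_params, "simulation")
  if (!is.null(x$seed)) sim_args$seed <- x$seed
  det <- x$detectors %||% list()
  bad_det <- setdiff(names(det), c("tos", "moving_window", "beam"))
  if (length(bad_det))
    config_error(paste0("unknown detectors key(s): ", paste(bad_det, collapse = ", ")))
  cfg <- list(
    seed = as.integer(x$seed %||% 1L),
    out_dir = x$out_dir %||% ".",
    simulation = do.call(simulation_params, sim_args),
    detectors = list(
      tos = do.call(tos_config, check_block(det$tos %||% list(), tos_config, "detectors$tos")),
      moving_window = do.call(window_config,
                              check_block(det$moving_window %||% list(), window_config,
                                          "detectors$moving_window")),
      beam = do.call(beam_config, check_block(det$beam %||% list(), beam_config,
                                              "detectors$beam"))),
    # the robust trend detector on the core channel stands in for the
    # study's gold-standard vaginal algorithm; strict TOS is too fragile
    # under noise and gaps to anchor a comparison
    reference_method = x$reference_method %||% "beam",
    test_method = x$test_method %||% "beam",
    tolerances = as.integer(x$tolerances %||% c(1L, 3L)),
    ci_level = x$ci_level %||% 0.95,
    representative = do.call(representative_config,
                             check_block(x$representative %||% list(),
                                         representative_config, "representative")))
  class(cfg) <- "run_config"
  cfg
}

resolved_config_list <- function(cfg) {
  lapply(cfg, function(el) if (is.list(el))
    lapply(el, function(e2) if (is.list(e2)) unclass(e2) else e2) else el)
}

#' Simulate a population and write it to disk
#'
#' Writes `cycles.csv` (both channels, long format), `truth.json` (ground
#' truth sidecar), and `resolved_config.json` under `out_dir`. Bit-identical
#' under an identical configuration and seed.
#'
#' @param config A [run_config()] (or anything it accepts).
#' @return Invisibly, a list with the generated pairs and output paths.
#' @export
cmd_simulate <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  pairs <- generate_population(cfg$simulation)
  cycles <- unlist(lapply(pairs, function(p) list(p$core_cycle, p$skin_cycle)),
                   recursive = FALSE)
  csv <- file.path(cfg$out_dir, "cycles.csv")
  sidecar <- file.path(cfg$out_dir, "truth.json")
  write_cycles(cycles, csv, sidecar = sidecar)
  cfg_path <- file.path(cfg$out_dir, "resolved_config.json")
  jsonlite::write_json(resolved_config_list(cfg), cfg_path,
                       auto_unbox = TRUE, digits = NA)
  invisible(list(pairs = pairs, cycles_csv = csv, truth_json = sidecar,
                 config_json = cfg_path))
}

#' Run detectors over a synthetic population
#'
#' The reference call is the configured reference detector applied to the
#' core (vaginal) channel; the test call is the configured test detector
#' applied to the skin channel. One row per cycle pair.
#'
#' @param pairs List of `synthetic_pair` objects.
#' @param cfg A [run_config()].
#' @return A data frame with participant/cycle identifiers, metadata, the
#'   reference and test calls, and the ground truth.
#' @export
detect_pairs <- function(pairs, cfg = run_config()) {
  if (!length(pairs))
    return(data.frame(participant_id = character(0), cycle_id = character(0),
                      cycle_length = integer(0), skin_site = character(0),
                      diagnosis = character(0), truth_day = integer(0),
                      ref_status = character(0), ref_day = integer(0),
                      test_status = character(0), test_day = integer(0)))
  rows <- lapply(pairs, function(p) {
    ref <- detect_cycle(p$core_cycle, cfg$reference_method,
                        cfg$detectors[[cfg$reference_method]],
                        cfg$representative)
    tst <- detect_cycle(p$skin_cycle, cfg$test_method,
                        cfg$detectors[[cfg$test_method]],
                        cfg$representative)
    data.frame(
      participant_id = p$core_cycle$participant_id,
      cycle_id = p$core_cycle$cycle_id,
      cycle_length = p$core_cycle$cycle_length,
      skin_site = p$skin_cycle$skin_site,
      diagnosis = p$core_cycle$diagnosis,
      truth_day = p$truth_ovulation_day,
      ref_status = ref$status, ref_day = ref$ovulation_day,
      test_status = tst$status, test_day = tst$ovulation_day,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

calls_from_df <- function(status, day, method = "reference") {
  mapply(function(s, d) {
    if (s == "positive") ovulation_call("positive", d, method)
    else ovulation_call("negative", method = method)
  }, status, day, SIMPLIFY = FALSE)
}

#' Threshold-method evaluation of detected calls
#'
#' Scores the test calls against the reference at each tolerance and
#' computes the full metric set, plus the days-difference summary over
#' cycles where both methods are positive.
#'
#' @param calls Data frame as returned by [detect_pairs()].
#' @param tolerances Integer vector of day tolerances (default `c(1, 3)`).
#' @param level Confidence level for intervals.
#' @return A list with `threshold` (long data frame of metrics),
#'   `counts` (one `confusion_counts` per tolerance), and `days_difference`.
#' @export
evaluate_calls <- function(calls, tolerances = c(1L, 3L), level = 0.95) {
  ref <- calls_from_df(calls$ref_status, calls$ref_day, "reference")
  tst <- calls_from_df(calls$test_status, calls$test_day, "beam")
  counts <- lapply(tolerances, function(tol) confusion_counts(tst, ref, tol))
  names(counts) <- paste0("pm", tolerances)
  threshold <- do.call(rbind, lapply(seq_along(tolerances), function(i) {
    m <- compute_metrics(counts[[i]], level)
    m$tolerance_days <- tolerances[i]
    as.data.frame(m)
  }))
  both <- calls$ref_status == "positive" & calls$test_status == "positive"
  dd <- days_difference_summary(calls$test_day[both], calls$ref_day[both], level)
  list(threshold = threshold, counts = counts, days_difference = dd)
}

#' Rolling subsequent-cycle prediction over a call table
#'
#' For each participant's cycles in order, predicts each cycle's ovulation
#' day from the participant's *previous* cycles (test-method history) and
#' scores the prediction against the reference confirmation for that cycle.
#' Cycles whose reference result is negative are excluded; the first cycle
#' of each participant has no history and is excluded too (no method could
#' predict it).
#'
#' @param calls Data frame as returned by [detect_pairs()].
#' @param tolerance_days Agreement window (default 3).
#' @param level Confidence level.
#' @param max_cycles History window for [predict_next_ovulation()].
#' @return A list with `counts` (a `confusion_counts`, TN identically 0),
#'   `metrics`, and `n_scored`.
#' @export
evaluate_prediction <- function(calls, tolerance_days = 3L, level = 0.95,
                                max_cycles = 12L) {
  tally <- c(TP = 0L, FP = 0L, FN = 0L)
  for (pid in unique(calls$participant_id)) {
    sub <- calls[calls$participant_id == pid, , drop = FALSE]
    if (nrow(sub) < 2L) next
    for (i in 2:nrow(sub)) {
      hist_test <- ifelse(sub$test_status[1:(i - 1)] == "positive",
                          sub$test_day[1:(i - 1)], NA_real_)
      hist_ref <- ifelse(sub$ref_status[1:(i - 1)] == "positive",
                         sub$ref_day[1:(i - 1)], NA_real_)
      pred <- predict_next_ovulation(hist_test, max_cycles)
      ref_pred <- predict_next_ovulation(hist_ref, max_cycles)
      actual <- if (sub$ref_status[i] == "positive")
        ovulation_call("positive", sub$ref_day[i], "reference")
      else ovulation_call("negative", method = "reference")
      res <- prediction_confusion(pred, actual, tolerance_days,
                                  reference_available = ref_pred$status == "predicted")
      if (res != "excluded") tally[res] <- tally[res] + 1L
    }
  }
  counts <- new_confusion_counts(tally["TP"], tally["FP"], 0L, tally["FN"],
                                 tolerance_days)
  list(counts = counts, metrics = compute_metrics(counts, level),
       n_scored = sum(tally))
}

#' Evaluate a simulated or recorded dataset and write report files
#'
#' Runs the full pipeline: detect on every cycle pair, threshold tables at
#' each tolerance, days-difference summary, ovulation-timing split, and the
#' subsequent-cycle prediction analysis. Writes one CSV per table family
#' plus a combined text report, and the resolved configuration.
#'
#' @param config A [run_config()] (or anything it accepts). When
#'   `pairs` is `NULL`, the population is simulated from the config.
#' @param pairs Optional pre-generated list of `synthetic_pair` objects.
#' @return Invisibly, a list of all computed tables.
#' @export
cmd_evaluate <- function(config = list(), pairs = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(pairs)) pairs <- generate_population(cfg$simulation)
  calls <- detect_pairs(pairs, cfg)
  ev <- evaluate_calls(calls, cfg$tolerances, cfg$ci_level)
  pred <- evaluate_prediction(calls, max(cfg$tolerances), cfg$ci_level)

  # timing split over reference-positive cycles
  pos <- calls[calls$ref_status == "positive" & !is.na(calls$cycle_length), ,
               drop = FALSE]
  timing <- if (nrow(pos)) vapply(seq_len(nrow(pos)), function(i)
    timing_class(pos$ref_day[i], pos$cycle_length[i])$label, character(1))
  else character(0)
  timing_tab <- as.data.frame(table(factor(timing,
                                           levels = c("early", "normal", "late"))))
  names(timing_tab) <- c("timing", "n_cycles")

  utils::write.csv(ev$threshold, file.path(cfg$out_dir, "threshold_metrics.csv"),
                   row.names = FALSE)
  if (!is.null(ev$days_difference))
    utils::write.csv(as.data.frame(unclass(ev$days_difference)),
                     file.path(cfg$out_dir, "days_difference.csv"),
                     row.names = FALSE)
  utils::write.csv(timing_tab, file.path(cfg$out_dir, "timing_groups.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(pred$metrics),
                   file.path(cfg$out_dir, "prediction_metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(resolved_config_list(cfg),
                       file.path(cfg$out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA)

  report <- file.path(cfg$out_dir, "report.txt")
  con <- file(report, "w"); on.exit(close(con), add = TRUE)
  writeLines(c(
    sprintf("ovutherm evaluation report (seed %d, %d cycle pairs)",
            cfg$seed, length(pairs)),
    sprintf("reference: %s on core channel; test: %s on skin channel",
            cfg$reference_method, cfg$test_method), ""), con)
  for (nm in names(ev$counts)) {
    cc <- ev$counts[[nm]]
    writeLines(sprintf("+/-%d days: TP %d  FP %d  TN %d  FN %d",
                       cc$tolerance_days, cc$tp, cc$fp, cc$tn, cc$fn), con)
    m <- round_metrics_for_report(
      compute_metrics(cc, cfg$ci_level))
    writeLines(sprintf("  %s", paste(names(m), m, sep = "=", collapse = "  ")), con)
  }
  if (!is.null(ev$days_difference)) {
    dd <- ev$days_difference
    writeLines(sprintf(
      "days difference (test - reference): n=%d mean=%.2f sd=%.2f CI=[%.2f, %.2f]",
      dd$n, dd$mean_diff, dd$sd_diff, dd$ci_low, dd$ci_high), con)
  }
  writeLines(sprintf(
    "prediction +/-%d days: TP %d FP %d FN %d; accuracy %.1f%%",
    pred$counts$tolerance_days, pred$counts$tp, pred$counts$fp, pred$counts$fn,
    100 * pred$metrics$value[pred$metrics$metric == "accuracy"]), con)

  invisible(list(calls = calls, evaluation = ev, prediction = pred,
                 timing = timing_tab, report = report))
}
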