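# Per-cycle ovulation confirmation from the nightly representative
# temperature series.
#
# Three detector families are provided:
#   * tos_detect            -- the strict "three over six" rule
#   * moving_window_detect  -- rolling-mean shift detection
#   * beam_detect           -- a robust exponentially-weighted trend detector,
#                              a reconstruction in the spirit of the
#                              "spring-loaded beam" family of proprietary
#                              algorithms (the published description names the
#                              idea but not the update rule; no equivalence to
#                              any commercial implementation is claimed).
#
# All detectors take a numeric vector `temps` where position d is the
# representative temperature of cycle day d and NA marks a missing night.
# All are deterministic, side-effect free, and stop at the first confirmed
# shift.

# Temperatures arrive rounded to 3 decimals; exact ">= 0.3 degC" comparisons
# need a guard against binary representation error.
EPS_TEMP <- 1e-8

#' A detector's per-cycle verdict
#'
#' @param status `"positive"` (ovulation confirmed) or `"negative"`
#'   (anovulatory / no confirmed shift).
#' @param ovulation_day The confirmed ovulation day; required iff positive.
#' @param method Which detector produced the call.
#' @param reason Optional qualifier for negative calls, e.g.
#'   `"insufficient_data"`.
#' @return An object of class `ovulation_call`.
#' @export
ovulation_call <- function(status = c("positive", "negative"),
                           ovulation_day = NA_integer_,
                           method = c("tos", "moving_window", "beam", "reference"),
                           reason = NULL) {
  status <- match.arg(status)
  method <- match.arg(method)
  ovulation_day <- as.integer(ovulation_day)
  if (status == "positive" && (is.na(ovulation_day) || ovulation_day < 1L))
    domain_error("positive calls must carry ovulation_day >= 1")
  if (status == "negative" && !is.na(ovulation_day))
    domain_error("negative calls must not carry an ovulation_day")
  structure(list(status = status, ovulation_day = ovulation_day,
                 method = method, reason = reason),
            class = "ovulation_call")
}

#' @export
print.ovulation_call <- function(x, ...) {
  cat(sprintf("<%s call: %s%s%s>\n", x$method, x$status,
              if (x$status == "positive") sprintf(", day %d", x$ovulation_day) else "",
              if (!is.null(x$reason)) sprintf(" (%s)", x$reason) else ""))
  invisible(x)
}

is_positive <- function(call) call$status == "positive"

#' Three-over-six rule configuration
#'
#' @param rise_threshold Minimum rise in deg C (default 0.30).
#' @param n_high Number of consecutive elevated nights required (default 3).
#' @param n_low Number of consecutive reference nights (default 6).
#' @param allow_gaps If `FALSE` (default) a missing night inside a candidate
#'   window disqualifies it; if `TRUE` windows run over observed nights only.
#' @param low_summary How the low window is summarized before comparison:
#'   `"max"` (strict reading, default) or `"mean"`.
#' @return An object of class `tos_config`.
#' @export
tos_config <- function(rise_threshold = 0.30, n_high = 3L, n_low = 6L,
                       allow_gaps = FALSE, low_summary = c("max", "mean")) {
  if (rise_threshold <= 0) config_error("rise_threshold must be > 0")
  n_high <- as.integer(n_high); n_low <- as.integer(n_low)
  if (n_high < 1L || n_low < 1L) config_error("n_high and n_low must be >= 1")
  structure(list(rise_threshold = rise_threshold, n_high = n_high,
                 n_low = n_low, allow_gaps = isTRUE(allow_gaps),
                 low_summary = match.arg(low_summary)),
            class = "tos_config")
}

#' Moving-window detector configuration
#'
#' @param window_len Nights per rolling window (default 3).
#' @param rise_threshold Required excess of a window mean over the running
#'   minimum of all preceding window means, in deg C (default 0.30).
#' @param confirm_nights Consecutive qualifying windows required (default 3).
#' @return An object of class `window_config`.
#' @export
window_config <- function(window_len = 3L, rise_threshold = 0.30,
                          confirm_nights = 3L) {
  window_len <- as.integer(window_len)
  confirm_nights <- as.integer(confirm_nights)
  if (window_len < 1L) config_error("window_len must be >= 1")
  if (confirm_nights < 1L) config_error("confirm_nights must be >= 1")
  if (rise_threshold <= 0) config_error("rise_threshold must be > 0")
  structure(list(window_len = window_len, rise_threshold = rise_threshold,
                 confirm_nights = confirm_nights),
            class = "window_config")
}

#' Robust trend ("beam") detector configuration
#'
#' @param half_life Weight half-life of the exponentially-weighted baseline,
#'   in nights (default 7): a night's influence on the baseline halves every
#'   `half_life` later nights.
#' @param residual_clip Residuals are clipped at this many multiples of the
#'   running robust scale before updating the baseline (default 3).
#' @param deflection_threshold Required excess of the raw nightly temperature
#'   over the baseline, in deg C (default 0.20).
#' @param confirm_nights Consecutive deflected nights required (default 3).
#' @param min_history Observed nights of history required before a
#'   confirmation may begin (default 6).
#' @return An object of class `beam_config`.
#' @export
beam_config <- function(half_life = 7, residual_clip = 3,
                        deflection_threshold = 0.20, confirm_nights = 3L,
                        min_history = 6L) {
  if (half_life <= 0) config_error("half_life must be > 0")
  confirm_nights <- as.integer(confirm_nights)
  if (confirm_nights < 1L) config_error("confirm_nights must be >= 1")
  if (deflection_threshold <= 0) config_error("deflection_threshold must be > 0")
  structure(list(half_life = half_life, residual_clip = residual_clip,
                 deflection_threshold = deflection_threshold,
                 confirm_nights = confirm_nights,
                 min_history = as.integer(min_history)),
            class = "beam_config")
}

negative_call <- function(method, reason = NULL)
  ovulation_call("negative", method = method, reason = reason)

#' Three-over-six ("TOS") shift detection
#'
#' Scans candidate windows in increasing day order: `n_low` consecutive
#' reference nights followed immediately by `n_high` consecutive elevated
#' nights. A window qualifies when every elevated-night temperature is at
#' least `rise_threshold` above the summary (default: maximum) of the
#' reference nights. The first qualifying window wins and the ovulation day
#' is the day before the first elevated night. With `allow_gaps = FALSE`
#' a missing night anywhere inside a candidate window disqualifies it —
#' the strict rule application that drives this method's false negatives on
#' sparse data.
#'
#' @param temps Numeric vector; position `d` = representative temperature of
#'   cycle day `d`, `NA` for a missing night.
#' @param config A [tos_config()].
#' @return An [ovulation_call()].
#' @export
tos_detect <- function(temps, config = tos_config()) {
  need <- config$n_low + config$n_high
  if (sum(!is.na(temps)) < need)
    return(negative_call("tos", "insufficient_data"))
  summarize_low <- if (config$low_summary == "max") max else mean
  if (!config$allow_gaps) {
    n <- length(temps)
    for (s in seq_len(max(0L, n - need + 1L))) {
      low  <- temps[s:(s + config$n_low - 1L)]
      high <- temps[(s + config$n_low):(s + need - 1L)]
      if (anyNA(low) || anyNA(high)) next
      if (min(high) - summarize_low(low) >= config$rise_threshold - EPS_TEMP)
        return(ovulation_call("positive", s + config$n_low - 1L, "tos"))
    }
  } else {
    obs <- which(!is.na(temps))
    m <- length(obs)
    for (j in seq_len(m - need + 1L)) {
      low  <- temps[obs[j:(j + config$n_low - 1L)]]
      high <- temps[obs[(j + config$n_low):(j + need - 1L)]]
      if (min(high) - summarize_low(low) >= config$rise_threshold - EPS_TEMP)
        return(ovulation_call("positive", obs[j + config$n_low] - 1L, "tos"))
    }
  }
  negative_call("tos")
}

#' Moving-window (rolling mean) shift detection
#'
#' Computes the mean of each rolling window of `window_len` observed nights.
#' A shift is confirmed when the rolling mean exceeds the minimum of all
#' preceding rolling means by at least `rise_threshold` for `confirm_nights`
#' consecutive windows; the ovulation day is the day before the first night
#' of the first confirming window.
#'
#' @inheritParams tos_detect
#' @param config A [window_config()].
#' @return An [ovulation_call()].
#' @export
moving_window_detect <- function(temps, config = window_config()) {
  obs <- which(!is.na(temps))
  m <- length(obs)
  if (m < config$window_len + config$confirm_nights)
    return(negative_call("moving_window", "insufficient_data"))
  n_win <- m - config$window_len + 1L
  means <- vapply(seq_len(n_win), function(j)
    mean(temps[obs[j:(j + config$window_len - 1L)]]), numeric(1))
  qualifies <- logical(n_win)
  run_min <- Inf
  for (j in seq_len(n_win)) {
    qualifies[j] <- is.finite(run_min) &&
      (means[j] - run_min >= config$rise_threshold - EPS_TEMP)
    run_min <- min(run_min, means[j])
  }
  run <- 0L
  for (j in seq_len(n_win)) {
    run <- if (qualifies[j]) run + 1L else 0L
    if (run == config$confirm_nights) {
      first <- j - config$confirm_nights + 1L
      return(ovulation_call("positive", obs[first] - 1L, "moving_window"))
    }
  }
  negative_call("moving_window")
}

#' Robust exponentially-weighted trend detection ("beam")
#'
#' Maintains, night by night over observed nights, an exponentially-weighted
#' baseline of prior nights (weights halving every `half_life` nights)
#' together with a running robust scale (exponentially-weighted mean absolute
#' residual). Each residual is clipped at `residual_clip` multiples of the
#' scale before it updates the baseline, so isolated spikes barely deflect
#' it, while a sustained rise accumulates. A shift is confirmed when the raw
#' nightly temperature exceeds the baseline by at least
#' `deflection_threshold` for `confirm_nights` consecutive observed nights,
#' once at least `min_history` nights of history exist; the ovulation day is
#' the day before the first confirming night.
#'
#' Nights inside an active candidate run are withheld from the baseline and
#' scale until the run fails (then absorbed, clipped, in order). This is the
#' usual out-of-control handling in change-point monitoring: a night that
#' may be the shift itself must not drag the null baseline up while it is
#' being tested.
#'
#' This is a documented reconstruction of the "spring-loaded beam" family of
#' detectors: robust to single-night noise, sensitive to sustained trends,
#' and tolerant of missing nights (it simply skips them).
#'
#' @inheritParams tos_detect
#' @param config A [beam_config()].
#' @return An [ovulation_call()].
#' @export
beam_detect <- function(temps, config = beam_config()) {
  obs <- which(!is.na(temps))
  m <- length(obs)
  if (m < config$min_history + config$confirm_nights)
    return(negative_call("beam", "insufficient_data"))
  alpha <- 1 - 2^(-1 / config$half_life)
  baseline <- temps[obs[1]]
  scale <- 0
  run <- 0L
  run_start <- NA_integer_
  buffer <- numeric(0)
  absorb <- function(x) {
    r <- x - baseline
    r_clip <- if (scale > EPS_TEMP)
      max(-config$residual_clip * scale, min(config$residual_clip * scale, r))
    else r
    baseline <<- baseline + alpha * r_clip
    scale <<- (1 - alpha) * scale + alpha * abs(r_clip)
  }
  for (j in 2:m) {
    x <- temps[obs[j]]
    r <- x - baseline
    # history = number of nights seen before this one
    if (j - 1L >= config$min_history &&
        r >= config$deflection_threshold - EPS_TEMP) {
      if (run == 0L) run_start <- obs[j]
      run <- run + 1L
      buffer <- c(buffer, x)
      if (run == config$confirm_nights)
        return(ovulation_call("positive", run_start - 1L, "beam"))
    } else {
      for (b in buffer) absorb(b)
      buffer <- numeric(0)
      run <- 0L
      run_start <- NA_integer_
      absorb(x)
    }
  }
  negative_call("beam")
}

#' Run a detector on a cycle
#'
#' Convenience wrapper: reduces each night to its representative overnight
#' temperature, then applies the chosen detector.
#'
#' @param cyc A [cycle()].
#' @param method `"tos"`, `"moving_window"`, or `"beam"`.
#' @param config Detector configuration; defaults to the method's default.
#' @param rep_config A [representative_config()].
#' @return An [ovulation_call()].
#' @export
detect_cycle <- function(cyc, method = c("tos", "moving_window", "beam"),
                         config = NULL,
                         rep_config = representative_config()) {
  method <- match.arg(method)
  temps <- cycle_temperatures(cyc, rep_config)
  switch(method,
         tos = tos_detect(temps, config %||% tos_config()),
         moving_window = moving_window_detect(temps, config %||% window_config()),
         beam = beam_detect(temps, config %||% beam_config()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
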