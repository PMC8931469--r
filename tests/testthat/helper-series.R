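# Shared fixtures: step series and an independent brute-force oracle for the
# three-over-six rule.

# Noise-free biphasic step: baseline, then baseline + shift from day
# truth_day + lag onward.
make_step <- function(len, truth_day, baseline = 36.40, shift = 0.40,
                      lag = 1L, noise_sd = 0) {
  t <- baseline + shift * (seq_len(len) >= truth_day + lag)
  if (noise_sd > 0) t <- t + stats::rnorm(len, 0, noise_sd)
  round(t, 3)
}

# Exhaustive scan of every (n_low, n_high) window, written independently of
# tos_detect: uses all() over the high days against max(low) + rise.
# Returns the ovulation day or NA.
tos_oracle <- function(temps, rise = 0.30, n_low = 6L, n_high = 3L) {
  n <- length(temps)
  width <- n_low + n_high
  if (n < width) return(NA_integer_)
  for (s in seq_len(n - width + 1L)) {
    low <- temps[s:(s + n_low - 1L)]
    high <- temps[(s + n_low):(s + width - 1L)]
    if (anyNA(low) || anyNA(high)) next
    if (all(high >= max(low) + rise - 1e-8)) return(s + n_low - 1L)
  }
  NA_integer_
}

# Random nightly series with occasional upward steps and missing nights.
random_series <- function(len = 30L, gap_prob = 0.1) {
  base <- runif(1, 36.1, 36.7)
  shift_day <- sample(c(NA, 8:(len - 4)), 1)
  t <- base + runif(len, -0.15, 0.15)
  if (!is.na(shift_day))
    t[shift_day:len] <- t[shift_day:len] + runif(1, 0.1, 0.6)
  t[runif(len) < gap_prob] <- NA
  round(t, 3)
}

# Quick positive-call constructor for evaluation tests.
pos_call <- function(day, method = "reference") ovulation_call("positive", day, method)
neg_call <- function(method = "reference") ovulation_call("negative", method = method)

# Independent oracle for the subsequent-cycle prediction rule: drop
# anovulatory entries, keep the most recent 12, sort, and pick the middle
# (odd) or the higher of the two middle values (even) by explicit indexing.
predict_oracle <- function(history, max_cycles = 12L) {
  days <- history[!is.na(history)]
  if (length(days) > max_cycles)
    days <- days[(length(days) - max_cycles + 1):length(days)]
  if (!length(days)) return(NA_integer_)
  s <- sort(days)
  k <- length(s)
  if (k %% 2 == 1) s[(k + 1) / 2] else max(s[k / 2], s[k / 2 + 1])
}

# Rebuild ovulation_call objects from the status/day columns of a
# detect_pairs() data frame.
calls_from_status <- function(status, day, method = "reference") {
  mapply(function(s, d) if (s == "positive") pos_call(d, method) else neg_call(method),
         status, day, SIMPLIFY = FALSE)
}
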