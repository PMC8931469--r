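# Synthetic biphasic-cycle simulator.
#
# The temperature model is a step function: a follicular plateau at the
# participant's baseline, then a luteal plateau `luteal_shift` degC higher
# beginning `shift_onset_lag` days after the true ovulation day, plus
# independent Gaussian nightly noise. Anovulatory cycles are flat. Each
# simulated cycle comes as a side-by-side pair: a vaginal "core" channel and
# a skin channel whose shift onset is lagged (typically earlier), attenuated,
# and noisier -- the three effects that make skin-worn sensors read
# differently from a core sensor.

#' Simulation parameters
#'
#' Defaults emulate the population structure of a side-by-side skin/vaginal
#' sensor study of women with ovulatory dysfunction: ~23% anovulatory
#' cycles, right-skewed cycle lengths with median 32 days, about a third of
#' ovulatory cycles ovulating later than 65% of the cycle, and a skin
#' channel that on average confirms ovulation about 1.5 days earlier than
#' the core channel.
#'
#' @param n_participants Number of participants.
#' @param cycles_per_participant Cycles recorded per participant.
#' @param baseline_temp_mean Population mean follicular temperature, degC.
#' @param baseline_sd_between Between-participant SD of the baseline, degC.
#' @param luteal_shift Height of the luteal step, degC.
#' @param shift_onset_lag Days after ovulation at which the core shift
#'   begins (default 1: the first elevated night is the day after
#'   ovulation, matching the three-over-six convention that the ovulation
#'   day is the day before the first high temperature).
#' @param noise_sd Nightly Gaussian noise SD on the core channel, degC.
#' @param readings_per_night Readings recorded per night.
#' @param within_night_sd SD of within-night reading jitter, degC.
#' @param anovulation_prob Probability a cycle is anovulatory (flat).
#' @param cycle_length_log_median Median cycle length, days.
#' @param cycle_length_log_sd SD of log cycle length (dimensionless).
#' @param late_ovulation_prob Probability an ovulatory cycle ovulates later
#'   than 65% of the cycle length.
#' @param skin_lag_days Mean signed lag of the skin shift onset relative to
#'   the core onset, days; negative = earlier. Per cycle the lag is drawn
#'   uniformly within +/-1 day of this mean and rounded to a whole day, so
#'   the population mean of the (integer) skin-minus-core detected-day
#'   difference equals `skin_lag_days`.
#' @param skin_attenuation Multiplier in (0, 1] applied to the shift on the
#'   skin channel.
#' @param skin_extra_noise_sd SD of an additional independent Gaussian noise
#'   term on the skin channel, degC (combined with `noise_sd` in quadrature).
#' @param missing_night_prob Probability any given night goes unrecorded
#'   (independently per night and channel).
#' @param long_cycle_prob Probability of a long-cycle outlier (default 0;
#'   such cycles are only generated when explicitly requested).
#' @param long_cycle_range Length range (days) for long-cycle outliers.
#' @param seed Integer seed; the whole population is a pure function of
#'   `params`.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_participants = 80L,
                              cycles_per_participant = 3L,
                              baseline_temp_mean = 36.40,
                              baseline_sd_between = 0.15,
                              luteal_shift = 0.40,
                              shift_onset_lag = 1L,
                              noise_sd = 0.07,
                              readings_per_night = 1L,
                              within_night_sd = 0.02,
                              anovulation_prob = 0.23,
                              cycle_length_log_median = 32,
                              cycle_length_log_sd = 0.30,
                              late_ovulation_prob = 0.335,
                              skin_lag_days = -1.5,
                              skin_attenuation = 0.9,
                              skin_extra_noise_sd = 0.05,
                              missing_night_prob = 0.05,
                              long_cycle_prob = 0,
                              long_cycle_range = c(167L, 290L),
                              seed = 1L) {
  p <- list(n_participants = as.integer(n_participants),
            cycles_per_participant = as.integer(cycles_per_participant),
            baseline_temp_mean = baseline_temp_mean,
            baseline_sd_between = baseline_sd_between,
            luteal_shift = luteal_shift,
            shift_onset_lag = as.integer(shift_onset_lag),
            noise_sd = noise_sd,
            readings_per_night = as.integer(readings_per_night),
            within_night_sd = within_night_sd,
            anovulation_prob = anovulation_prob,
            cycle_length_log_median = cycle_length_log_median,
            cycle_length_log_sd = cycle_length_log_sd,
            late_ovulation_prob = late_ovulation_prob,
            skin_lag_days = skin_lag_days,
            skin_attenuation = skin_attenuation,
            skin_extra_noise_sd = skin_extra_noise_sd,
            missing_night_prob = missing_night_prob,
            long_cycle_prob = long_cycle_prob,
            long_cycle_range = as.integer(long_cycle_range),
            seed = as.integer(seed))
  for (nm in c("anovulation_prob", "late_ovulation_prob",
               "missing_night_prob", "long_cycle_prob")) {
    if (p[[nm]] < 0 || p[[nm]] > 1)
      config_error(sprintf("%s must lie in [0, 1]", nm))
  }
  if (p$luteal_shift < 0) config_error("luteal_shift must be >= 0")
  if (p$skin_attenuation <= 0 || p$skin_attenuation > 1)
    config_error("skin_attenuation must lie in (0, 1]")
  if (p$n_participants < 1L || p$cycles_per_participant < 1L)
    config_error("n_participants and cycles_per_participant must be >= 1")
  structure(p, class = "simulation_params")
}

DIAGNOSIS_WEIGHTS <- c(pcos = 0.43, hypothyroid = 0.02,
                       pcos_and_hypothyroid = 0.05,
                       confirmed_no_diagnosis = 0.40, undeclared = 0.10)

# Cycle length: log-normal with the configured log-median, resampled to stay
# >= 21 days; with probability long_cycle_prob replaced by a uniform draw
# from the long-cycle outlier range.
draw_cycle_length <- function(params) {
  if (params$long_cycle_prob > 0 && stats::runif(1) < params$long_cycle_prob)
    return(sample(params$long_cycle_range[1]:params$long_cycle_range[2], 1L))
  for (i in 1:100) {
    len <- round(stats::rlnorm(1, log(params$cycle_length_log_median),
                               params$cycle_length_log_sd))
    if (len >= 21) return(as.integer(len))
  }
  21L
}

# Ovulation day as a fraction of cycle length: late (>65%) with the
# configured probability, uniform within (0.65, 0.85]; otherwise uniform in
# (0.38, 0.65], which leaves a small early (<40%) tail like the study's
# 6/158 early cycles. Day is clamped so the luteal plateau is observable
# (>= 7 so a six-night reference window exists, <= length - 3 so three
# elevated nights exist).
draw_ovulation_day <- function(len, params) {
  frac <- if (stats::runif(1) < params$late_ovulation_prob)
    stats::runif(1, 0.65, 0.85) else stats::runif(1, 0.38, 0.65)
  day <- round(frac * len)
  as.integer(min(max(day, 7L), len - 3L))
}

build_channel <- function(len, baseline, shift, onset_day, noise_sd, params) {
  elevated <- if (is.na(onset_day)) rep(FALSE, len) else seq_len(len) >= onset_day
  nightly <- baseline + shift * elevated +
    if (noise_sd > 0) stats::rnorm(len, 0, noise_sd) else 0
  keep <- if (params$missing_night_prob > 0)
    stats::runif(len) >= params$missing_night_prob else rep(TRUE, len)
  nights <- list()
  for (d in seq_len(len)) {
    if (!keep[d]) next
    k <- params$readings_per_night
    reads <- nightly[d] +
      if (k > 1L && params$within_night_sd > 0)
        stats::rnorm(k, 0, params$within_night_sd) else rep(0, k)
    reads <- round(pmin(pmax(reads, TEMP_MIN), TEMP_MAX), 3)
    times <- if (k > 1L) sprintf("%02d:00", seq_len(k)) else NA_character_
    nights[[length(nights) + 1L]] <- night_record(d, reads, times)
  }
  nights
}

#' Generate one synthetic side-by-side cycle pair
#'
#' Draws one cycle for one participant on both channels. Uses the current
#' RNG state; [generate_population()] seeds it. With probability
#' `anovulation_prob` both channels are flat (truth absent); otherwise the
#' core shift begins `shift_onset_lag` days after the true ovulation day and
#' the skin shift onset is additionally offset by an integer per-cycle lag
#' centred on `skin_lag_days`.
#'
#' @param params A [simulation_params()].
#' @param participant_id,cycle_id Identifiers for the emitted cycles.
#' @param baseline Participant's follicular baseline, degC (drawn by
#'   [generate_population()]; defaults to the population mean).
#' @param skin_site,diagnosis Metadata carried onto the emitted cycles.
#' @return A list of class `synthetic_pair` with elements `core_cycle`,
#'   `skin_cycle`, `truth_ovulation_day`.
#' @export
generate_cycle_pair <- function(params, participant_id = "p1", cycle_id = "c1",
                                baseline = params$baseline_temp_mean,
                                skin_site = "arm", diagnosis = "undeclared") {
  len <- draw_cycle_length(params)
  anov <- stats::runif(1) < params$anovulation_prob
  truth <- if (anov) NA_integer_ else draw_ovulation_day(len, params)
  core_onset <- if (anov) NA_integer_ else truth + params$shift_onset_lag
  skin_lag <- if (anov) 0L else
    as.integer(round(stats::runif(1, params$skin_lag_days - 1,
                                  params$skin_lag_days + 1)))
  skin_onset <- if (anov) NA_integer_ else max(2L, core_onset + skin_lag)
  core_nights <- build_channel(len, baseline, params$luteal_shift, core_onset,
                               params$noise_sd, params)
  skin_noise <- sqrt(params$noise_sd^2 + params$skin_extra_noise_sd^2)
  skin_nights <- build_channel(len, baseline,
                               params$luteal_shift * params$skin_attenuation,
                               skin_onset, skin_noise, params)
  core <- cycle(participant_id, cycle_id, core_nights, cycle_length = len,
                end_logged = TRUE, sensor = "vaginal", skin_site = "none",
                diagnosis = diagnosis, truth_ovulation_day = truth)
  skin <- cycle(participant_id, cycle_id, skin_nights, cycle_length = len,
                end_logged = TRUE, sensor = "skin", skin_site = skin_site,
                diagnosis = diagnosis, truth_ovulation_day = truth)
  structure(list(core_cycle = core, skin_cycle = skin,
                 truth_ovulation_day = truth),
            class = "synthetic_pair")
}

#' Generate a synthetic study population
#'
#' `n_participants x cycles_per_participant` side-by-side pairs. Each
#' participant gets one baseline offset (SD `baseline_sd_between`), one skin
#' site (~25% wrist), and one diagnosis group, reused across their cycles.
#' Deterministic given `params` (including `params$seed`); the caller's RNG
#' state is left untouched.
#'
#' @param params A [simulation_params()].
#' @return List of `synthetic_pair` objects.
#' @export
generate_population <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(params$seed)
  pairs <- list()
  for (i in seq_len(params$n_participants)) {
    pid <- sprintf("P%03d", i)
    baseline <- params$baseline_temp_mean +
      if (params$baseline_sd_between > 0)
        stats::rnorm(1, 0, params$baseline_sd_between) else 0
    site <- if (stats::runif(1) < 0.25) "wrist" else "arm"
    diagnosis <- sample(names(DIAGNOSIS_WEIGHTS), 1L, prob = DIAGNOSIS_WEIGHTS)
    for (j in seq_len(params$cycles_per_participant)) {
      pairs[[length(pairs) + 1L]] <- generate_cycle_pair(
        params, pid, sprintf("C%02d", j), baseline = baseline,
        skin_site = site, diagnosis = diagnosis)
    }
  }
  pairs
}
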