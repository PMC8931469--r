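noise_free <- function(...) simulation_params(
  noise_sd = 0, within_night_sd = 0, skin_extra_noise_sd = 0,
  missing_night_prob = 0, baseline_sd_between = 0, ...)

test_that("noise-free cycles are exact step functions", {
  p <- noise_free(n_participants = 1, cycles_per_participant = 1,
                  anovulation_prob = 0, seed = 4)
  pair <- generate_population(p)[[1]]
  truth <- pair$truth_ovulation_day
  len <- pair$core_cycle$cycle_length
  temps <- cycle_temperatures(pair$core_cycle)
  expect_equal(temps[seq_len(truth)], rep(36.40, truth))
  expect_equal(temps[(truth + 1):len], rep(36.80, len - truth))
})

test_that("anovulatory cycles are flat on both channels with truth absent", {
  p <- noise_free(n_participants = 2, cycles_per_participant = 2,
                  anovulation_prob = 1, seed = 5)
  for (pair in generate_population(p)) {
    expect_true(is.na(pair$truth_ovulation_day))
    expect_true(is.na(pair$core_cycle$truth_ovulation_day))
    expect_true(is.na(pair$skin_cycle$truth_ovulation_day))
    expect_equal(length(unique(cycle_temperatures(pair$core_cycle))), 1L)
    expect_equal(length(unique(cycle_temperatures(pair$skin_cycle))), 1L)
  }
})

test_that("identical seed and parameters give bit-identical populations", {
  a <- generate_population(simulation_params(n_participants = 4, seed = 11))
  b <- generate_population(simulation_params(n_participants = 4, seed = 11))
  expect_identical(a, b)
  c <- generate_population(simulation_params(n_participants = 4, seed = 12))
  expect_false(identical(a, c))
})

test_that("generate_population does not disturb the caller's RNG stream", {
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_population(simulation_params(n_participants = 2)))
  expect_identical(runif(3), before)
})

test_that("population counts and shared pair structure hold", {
  p <- simulation_params(n_participants = 5, cycles_per_participant = 3, seed = 2)
  pop <- generate_population(p)
  expect_length(pop, 15)
  for (pair in pop) {
    expect_equal(pair$core_cycle$participant_id, pair$skin_cycle$participant_id)
    expect_equal(pair$core_cycle$cycle_id, pair$skin_cycle$cycle_id)
    expect_equal(pair$core_cycle$cycle_length, pair$skin_cycle$cycle_length)
    expect_equal(pair$core_cycle$truth_ovulation_day,
                 pair$skin_cycle$truth_ovulation_day)
    expect_equal(pair$core_cycle$sensor, "vaginal")
    expect_equal(pair$skin_cycle$sensor, "skin")
    expect_true(pair$core_cycle$cycle_length >= 21)
  }
  expect_length(generate_population(
    simulation_params(n_participants = 1, cycles_per_participant = 1)), 1)
})

test_that("anovulatory fraction stays within exact binomial bounds of its rate", {
  pop <- generate_population(simulation_params(
    n_participants = 80, cycles_per_participant = 3, seed = 21))
  n <- length(pop)
  k <- sum(vapply(pop, function(p) is.na(p$truth_ovulation_day), logical(1)))
  # 99% binomial envelope at p = 0.23, computed from the exact distribution
  expect_gte(k, qbinom(0.005, n, 0.23))
  expect_lte(k, qbinom(0.995, n, 0.23))
})

test_that("cycle length distribution is right-skewed with median near 32", {
  pop <- generate_population(simulation_params(
    n_participants = 250, cycles_per_participant = 4, seed = 31))
  lens <- vapply(pop, function(p) p$core_cycle$cycle_length, integer(1))
  expect_lt(abs(median(lens) - 32), 2)
  expect_gt(mean(lens), median(lens))  # right skew
  expect_true(all(lens >= 21))
})

test_that("late-ovulation mass matches its configured probability", {
  pop <- generate_population(simulation_params(
    n_participants = 300, cycles_per_participant = 2, anovulation_prob = 0,
    seed = 41))
  frac <- vapply(pop, function(p)
    p$truth_ovulation_day / p$core_cycle$cycle_length, numeric(1))
  n <- length(frac)
  k <- sum(frac > 0.65)
  expect_gte(k, qbinom(0.005, n, 0.335))
  expect_lte(k, qbinom(0.995, n, 0.335))
  expect_gt(sum(frac < 0.40), 0)  # small early tail exists
})

test_that("skin channel confirms earlier than core by the configured mean lag", {
  pop <- generate_population(noise_free(
    n_participants = 150, cycles_per_participant = 3, anovulation_prob = 0,
    seed = 51))
  diffs <- vapply(pop, function(pair) {
    core <- tos_detect(cycle_temperatures(pair$core_cycle))
    skin <- tos_detect(cycle_temperatures(pair$skin_cycle))
    if (core$status == "positive" && skin$status == "positive")
      skin$ovulation_day - core$ovulation_day else NA_real_
  }, numeric(1))
  diffs <- diffs[!is.na(diffs)]
  expect_gt(length(diffs), 300)
  expect_lt(abs(mean(diffs) - (-1.5)), 0.25)
  expect_true(all(diffs <= 0))
})

test_that("long-cycle outliers appear only when requested", {
  none <- generate_population(simulation_params(
    n_participants = 100, cycles_per_participant = 2, seed = 61))
  expect_true(all(vapply(none, function(p) p$core_cycle$cycle_length,
                         integer(1)) < 167))
  some <- generate_population(simulation_params(
    n_participants = 100, cycles_per_participant = 2, long_cycle_prob = 0.1,
    seed = 61))
  lens <- vapply(some, function(p) p$core_cycle$cycle_length, integer(1))
  expect_gt(sum(lens >= 167), 0)
  expect_true(all(lens[lens >= 167] <= 290))
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(simulation_params(anovulation_prob = 1.2),
               class = "ovutherm_config_error")
  expect_error(simulation_params(luteal_shift = -0.1),
               class = "ovutherm_config_error")
  expect_error(simulation_params(skin_attenuation = 0),
               class = "ovutherm_config_error")
})
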