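# Domain types and CSV input/output for nightly temperature cycles.
#
# A cycle is one participant's reproductive cycle: an ordered list of nights
# (cycle day 1 = first day of menstruation), each night holding zero or more
# timestamped temperature readings in degrees Celsius.

TEMP_MIN <- 30.0
TEMP_MAX <- 45.0

SENSOR_LEVELS    <- c("skin", "vaginal")
SKIN_SITE_LEVELS <- c("arm", "wrist", "none")
DIAGNOSIS_LEVELS <- c("pcos", "hypothyroid", "pcos_and_hypothyroid",
                      "confirmed_no_diagnosis", "undeclared")

#' One night's temperature readings
#'
#' @param cycle_day Integer cycle day, 1-based (day 1 = first day of menses).
#' @param temps Numeric vector of temperatures in deg C (may be empty for a
#'   missing night). All values must lie in \[30, 45\] deg C.
#' @param clock_times Optional character vector of reading times, recycled or
#'   `NA` when not recorded; same length as `temps`.
#' @return An object of class `night_record`.
#' @export
night_record <- function(cycle_day, temps = numeric(0), clock_times = NULL) {
  cycle_day <- as.integer(cycle_day)
  if (length(cycle_day) != 1L || is.na(cycle_day) || cycle_day < 1L)
    domain_error("cycle_day must be a single integer >= 1")
  temps <- as.numeric(temps)
  if (anyNA(temps))
    domain_error("night readings must not contain NA temperatures")
  if (length(temps) && (any(temps < TEMP_MIN) || any(temps > TEMP_MAX)))
    domain_error(sprintf("temperatures must lie in [%.1f, %.1f] degC", TEMP_MIN, TEMP_MAX))
  if (is.null(clock_times)) clock_times <- rep(NA_character_, length(temps))
  clock_times <- as.character(clock_times)
  if (length(clock_times) != length(temps))
    domain_error("clock_times must have one entry per reading")
  structure(
    list(cycle_day = cycle_day, temps = temps, clock_times = clock_times),
    class = "night_record"
  )
}

#' @export
print.night_record <- function(x, ...) {
  cat(sprintf("night %d: %s\n", x$cycle_day,
              if (length(x$temps)) paste(sprintf("%.3f", x$temps), collapse = ", ")
              else "(missing)"))
  invisible(x)
}

#' A participant's reproductive cycle
#'
#' @param participant_id,cycle_id Opaque identifier strings.
#' @param nights List of [night_record()] objects, strictly increasing in
#'   `cycle_day`.
#' @param cycle_length Cycle length in days, or `NA` when the participant
#'   never logged a cycle end date.
#' @param end_logged Logical: did the participant log the cycle end date?
#' @param sensor `"skin"` or `"vaginal"`.
#' @param skin_site `"arm"`, `"wrist"`, or `"none"` (for the vaginal channel).
#' @param diagnosis Prior diagnosis group.
#' @param truth_ovulation_day Ground-truth ovulation day (synthetic cycles
#'   only) or `NA`; `NA` marks an anovulatory cycle.
#' @return An object of class `cycle`.
#' @export
cycle <- function(participant_id, cycle_id, nights = list(),
                  cycle_length = NA_integer_, end_logged = FALSE,
                  sensor = "vaginal", skin_site = "none",
                  diagnosis = "undeclared",
                  truth_ovulation_day = NA_integer_) {
  sensor    <- match.arg(sensor, SENSOR_LEVELS)
  skin_site <- match.arg(skin_site, SKIN_SITE_LEVELS)
  diagnosis <- match.arg(diagnosis, DIAGNOSIS_LEVELS)
  if (!all(vapply(nights, inherits, logical(1), "night_record")))
    domain_error("nights must be a list of night_record objects")
  days <- vapply(nights, `[[`, integer(1), "cycle_day")
  if (length(days) && any(diff(days) <= 0L))
    domain_error("nights must be strictly increasing in cycle_day")
  cycle_length <- as.integer(cycle_length)
  end_logged <- isTRUE(end_logged)
  if (end_logged) {
    if (is.na(cycle_length))
      domain_error("end_logged cycles must carry a cycle_length")
    if (length(days) && cycle_length < max(days))
      domain_error("cycle_length must be >= the last recorded cycle_day")
  }
  truth_ovulation_day <- as.integer(truth_ovulation_day)
  if (!is.na(truth_ovulation_day) &&
      (truth_ovulation_day < 1L ||
       (!is.na(cycle_length) && truth_ovulation_day > cycle_length)))
    domain_error("truth_ovulation_day must lie in [1, cycle_length]")
  structure(
    list(participant_id = as.character(participant_id),
         cycle_id = as.character(cycle_id),
         nights = nights, cycle_length = cycle_length,
         end_logged = end_logged, sensor = sensor, skin_site = skin_site,
         diagnosis = diagnosis, truth_ovulation_day = truth_ovulation_day),
    class = "cycle"
  )
}

#' @export
print.cycle <- function(x, ...) {
  cat(sprintf("<cycle %s/%s: %d nights, length %s, sensor %s%s>\n",
              x$participant_id, x$cycle_id, length(x$nights),
              ifelse(is.na(x$cycle_length), "?", x$cycle_length), x$sensor,
              if (!is.na(x$truth_ovulation_day))
                sprintf(", truth day %d", x$truth_ovulation_day) else ""))
  invisible(x)
}

#' Configuration for the nightly reduction
#'
#' Controls how a night's multiple readings collapse to one representative
#' overnight temperature.
#'
#' @param reducer `"median"` (default) or `"trimmed_mean"`.
#' @param trim_fraction Proportion trimmed from each tail for
#'   `"trimmed_mean"`; must lie in \[0, 0.5).
#' @param min_readings Minimum readings needed before a night yields a
#'   representative value.
#' @return An object of class `representative_config`.
#' @export
representative_config <- function(reducer = c("median", "trimmed_mean"),
                                  trim_fraction = 0.1, min_readings = 1L) {
  reducer <- match.arg(reducer)
  if (!is.numeric(trim_fraction) || trim_fraction < 0 || trim_fraction >= 0.5)
    config_error("trim_fraction must lie in [0, 0.5)")
  min_readings <- as.integer(min_readings)
  if (is.na(min_readings) || min_readings < 1L)
    config_error("min_readings must be an integer >= 1")
  structure(list(reducer = reducer, trim_fraction = trim_fraction,
                 min_readings = min_readings),
            class = "representative_config")
}

#' Representative overnight temperature of one night
#'
#' Collapses the (possibly multiple) readings of one night to a single
#' robust value. Returns `NA` when the night has fewer than
#' `config$min_readings` readings; a single reading is returned unchanged
#' under any reducer.
#'
#' @param night A [night_record()].
#' @param config A [representative_config()].
#' @return A single temperature in deg C, or `NA`.
#' @export
representative_overnight_temperature <- function(night,
                                                 config = representative_config()) {
  stopifnot(inherits(night, "night_record"))
  if (length(night$temps) < config$min_readings) return(NA_real_)
  switch(config$reducer,
         median = stats::median(night$temps),
         trimmed_mean = mean(night$temps, trim = config$trim_fraction))
}

#' Nightly representative temperature series of a cycle
#'
#' @param cyc A [cycle()].
#' @param config A [representative_config()].
#' @param n_days Length of the returned series; defaults to the cycle length
#'   when known, otherwise the last recorded night.
#' @return Numeric vector where position `d` holds the representative
#'   temperature of cycle day `d`, `NA` on missing nights.
#' @export
cycle_temperatures <- function(cyc, config = representative_config(),
                               n_days = NULL) {
  stopifnot(inherits(cyc, "cycle"))
  if (is.null(n_days)) {
    n_days <- if (!is.na(cyc$cycle_length)) cyc$cycle_length
              else if (length(cyc$nights))
                max(vapply(cyc$nights, `[[`, integer(1), "cycle_day"))
              else 0L
  }
  out <- rep(NA_real_, n_days)
  for (n in cyc$nights) {
    if (n$cycle_day <= n_days)
      out[n$cycle_day] <- representative_overnight_temperature(n, config)
  }
  out
}

#' Partition cycles by the study inclusion rule
#'
#' Cycles without a logged end date (or without a determinable cycle length)
#' are excluded from analysis; everything else is included. Input order is
#' preserved and the two parts partition the input.
#'
#' @param cycles List of [cycle()] objects.
#' @return A list with elements `included` and `excluded`.
#' @export
apply_inclusion <- function(cycles) {
  keep <- vapply(cycles, function(cc) isTRUE(cc$end_logged) && !is.na(cc$cycle_length),
                 logical(1))
  list(included = cycles[keep], excluded = cycles[!keep])
}

default_schema <- function() {
  c(participant_id = "participant_id", cycle_id = "cycle_id",
    cycle_day = "cycle_day", temp_c = "temp_c", clock_time = "clock_time",
    sensor = "sensor", skin_site = "skin_site", diagnosis = "diagnosis",
    cycle_length = "cycle_length", end_logged = "end_logged")
}

#' Read cycles from a long-format CSV
#'
#' Expects one row per reading with a header; multiple rows sharing a
#' (participant, cycle, day) become multiple readings of one night. Required
#' columns: `participant_id`, `cycle_id`, `cycle_day`, `temp_c`. Optional:
#' `clock_time`, `sensor`, `skin_site`, `diagnosis`, `cycle_length`,
#' `end_logged`. Column names can be remapped through `schema`.
#'
#' @param path CSV file path.
#' @param schema Named character vector mapping standard names (names) to
#'   the file's column names (values); unspecified entries fall back to the
#'   standard names.
#' @param sidecar Optional path to a JSON sidecar (as written by
#'   [write_cycles()]) carrying per-cycle metadata such as the synthetic
#'   ground-truth ovulation day.
#' @return List of [cycle()] objects, in first-appearance order.
#' @export
read_cycles <- function(path, schema = NULL, sidecar = NULL) {
  sch <- default_schema()
  if (!is.null(schema)) {
    unknown <- setdiff(names(schema), names(sch))
    if (length(unknown))
      schema_error(paste0("unknown schema key(s): ", paste(unknown, collapse = ", ")))
    sch[names(schema)] <- schema
  }
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        strip.white = TRUE)
  required <- c("participant_id", "cycle_id", "cycle_day", "temp_c")
  for (col in required) {
    if (!sch[[col]] %in% names(df))
      schema_error(sprintf("required column '%s' missing from %s", sch[[col]], path))
  }
  get_col <- function(std) {
    nm <- sch[[std]]
    if (nm %in% names(df)) df[[nm]] else rep(NA_character_, nrow(df))
  }
  temp_raw <- get_col("temp_c")
  temp <- suppressWarnings(as.numeric(temp_raw))
  bad <- which(is.na(temp) & nzchar(temp_raw) & !is.na(temp_raw))
  if (length(bad))
    data_error(sprintf("unparsable temperature %s on data row %d of %s",
                       dQuote(temp_raw[bad[1]]), bad[1], path))
  day <- suppressWarnings(as.integer(get_col("cycle_day")))
  if (anyNA(day))
    data_error(sprintf("unparsable cycle_day on data row %d of %s",
                       which(is.na(day))[1], path))
  clock <- get_col("clock_time")
  sensor_col <- get_col("sensor")
  # one cycle object per (participant, cycle, sensor channel)
  cyc_key <- paste(get_col("participant_id"), get_col("cycle_id"),
                   sensor_col, sep = "\r")
  # only rows with an explicit clock time can collide; untimed repeat
  # readings on one night are legitimate
  timed <- !is.na(clock) & nzchar(clock)
  key <- paste(cyc_key, day, clock, sep = "\r")[timed]
  if (anyDuplicated(key))
    data_error(sprintf("duplicate (participant, cycle, day, clock_time) on data row %d",
                       which(timed)[which(duplicated(key))[1]]))
  meta <- if (!is.null(sidecar)) jsonlite::read_json(sidecar, simplifyVector = FALSE) else NULL
  out <- list()
  for (k in unique(cyc_key)) {
    rows <- which(cyc_key == k)
    first <- rows[1]
    nights <- lapply(sort(unique(day[rows])), function(d) {
      rr <- rows[day[rows] == d]
      rr <- rr[order(clock[rr])]
      night_record(d, temp[rr], clock[rr])
    })
    one <- function(std, default) {
      v <- get_col(std)[first]
      if (is.na(v) || !nzchar(v)) default else v
    }
    clen <- suppressWarnings(as.integer(one("cycle_length", NA)))
    elog <- tolower(one("end_logged", "false")) %in% c("true", "t", "1", "yes")
    cid <- get_col("cycle_id")[first]
    pid <- get_col("participant_id")[first]
    truth <- NA_integer_
    if (!is.null(meta)) {
      m <- meta[[paste(pid, cid, sep = "/")]]
      if (!is.null(m) && !is.null(m$truth_ovulation_day))
        truth <- as.integer(m$truth_ovulation_day)
    }
    out[[length(out) + 1L]] <- cycle(
      pid, cid, nights, cycle_length = clen, end_logged = elog,
      sensor = one("sensor", "vaginal"), skin_site = one("skin_site", "none"),
      diagnosis = one("diagnosis", "undeclared"), truth_ovulation_day = truth)
  }
  out
}

#' Write cycles to a long-format CSV (plus optional JSON sidecar)
#'
#' Temperatures are serialized to 3 decimal places, matching the 0.003 degC
#' resolution of the sensors the package models; [read_cycles()] of the
#' result round-trips every field.
#'
#' @param cycles List of [cycle()] objects.
#' @param path Output CSV path.
#' @param sidecar Optional JSON path; when given, per-cycle ground truth
#'   (`truth_ovulation_day`) is written there keyed by
#'   `"participant_id/cycle_id"`.
#' @return `path`, invisibly.
#' @export
write_cycles <- function(cycles, path, sidecar = NULL) {
  rows <- list()
  for (cc in cycles) {
    for (n in cc$nights) {
      if (!length(n$temps)) next
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = cc$participant_id, cycle_id = cc$cycle_id,
        cycle_day = n$cycle_day,
        clock_time = ifelse(is.na(n$clock_times), "", n$clock_times),
        temp_c = sprintf("%.3f", n$temps),
        sensor = cc$sensor, skin_site = cc$skin_site,
        diagnosis = cc$diagnosis,
        cycle_length = ifelse(is.na(cc$cycle_length), "", cc$cycle_length),
        end_logged = tolower(as.character(cc$end_logged)),
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(participant_id = character(0), cycle_id = character(0),
               cycle_day = integer(0), clock_time = character(0),
               temp_c = character(0), sensor = character(0),
               skin_site = character(0), diagnosis = character(0),
               cycle_length = character(0), end_logged = character(0))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(sidecar)) {
    meta <- list()
    for (cc in cycles) {
      meta[[paste(cc$participant_id, cc$cycle_id, sep = "/")]] <-
        list(truth_ovulation_day =
               if (is.na(cc$truth_ovulation_day)) NULL else cc$truth_ovulation_day)
    }
    jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}
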