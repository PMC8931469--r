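# Subsequent-cycle ovulation prediction.
#
# When a new cycle starts, the predicted ovulation day is the median of the
# confirmed ovulation days over (up to) the 12 most recent previous
# ovulatory cycles, with anovulatory cycles ignored. Because cycle days are
# discrete, the median is constrained to a day that actually occurred: with
# an even number of retained cycles, the HIGHER of the two middle values is
# taken.

#' Predicted ovulation for a newly started cycle
#'
#' @param history Either a numeric vector of per-cycle confirmed ovulation
#'   days ordered oldest to newest, with `NA` marking anovulatory cycles, or
#'   a list of [ovulation_call()] objects in the same order.
#' @param max_cycles Maximum number of previous ovulatory cycles used
#'   (default 12).
#' @param window `"ovulatory"` (default): keep the `max_cycles` most recent
#'   *ovulatory* cycles, skipping over interleaved anovulatory ones;
#'   `"all"`: restrict to the last `max_cycles` cycles of any kind first,
#'   then drop the anovulatory ones.
#' @return An object of class `predicted_ovulation`: a list with `status`
#'   (`"predicted"` or `"unavailable"`), `day` (integer or `NA`), and
#'   `n_cycles_used`. The returned day is always a member of the retained
#'   history, never an interpolated value.
#' @export
predict_next_ovulation <- function(history, max_cycles = 12L,
                                   window = c("ovulatory", "all")) {
  window <- match.arg(window)
  if (is.list(history)) {
    history <- vapply(history, function(h) {
      stopifnot(inherits(h, "ovulation_call"))
      if (is_positive(h)) as.numeric(h$ovulation_day) else NA_real_
    }, numeric(1))
  }
  history <- as.numeric(history)
  if (window == "all" && length(history) > max_cycles)
    history <- utils::tail(history, max_cycles)
  days <- history[!is.na(history)]
  if (length(days) > max_cycles) days <- utils::tail(days, max_cycles)
  if (!length(days))
    return(structure(list(status = "unavailable", day = NA_integer_,
                          n_cycles_used = 0L),
                     class = "predicted_ovulation"))
  sorted <- sort(days)
  k <- length(sorted)
  # odd k: exact middle; even k: higher of the two middle values
  day <- sorted[k %/% 2L + 1L]
  structure(list(status = "predicted", day = as.integer(day),
                 n_cycles_used = k),
            class = "predicted_ovulation")
}

#' @export
print.predicted_ovulation <- function(x, ...) {
  if (x$status == "predicted")
    cat(sprintf("<predicted ovulation: day %d (from %d cycles)>\n",
                x$day, x$n_cycles_used))
  else cat("<predicted ovulation: unavailable>\n")
  invisible(x)
}
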