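#' Build an ingestion schedule
#'
#' An ingestion schedule is a set of non-overlapping events, each delivering
#' `grams` of glucose at a constant rate over `[start, start + duration)`.
#' The ingestion flux of an event is `grams / duration` g/min; a "bolus" is
#' by convention a single 0.5-min event, so a 50-g bolus has flux
#' 50 / 0.5 = 100 g/min.
#'
#' @param start Numeric vector of event start times (min).
#' @param grams Numeric vector of event doses (g), strictly positive.
#' @param duration Numeric vector of event durations (min), strictly
#'   positive; recycled to the length of `start`.
#' @return A tibble of class `ogtt_schedule` with columns `start`, `grams`,
#'   `duration`, sorted by `start`.
#' @examples
#' bolus_schedule(50)                 # one 0.5-min event, flux 100 g/min
#' continuous_schedule(75, 120)       # 2-h continuous, flux 0.625 g/min
#' ingestion_schedule(c(0, 60), c(1, 49), 0.5)
#' @export
ingestion_schedule <- function(start, grams, duration = 0.5) {
  n <- length(start)
  duration <- rep_len(duration, n)
  stopifnot(length(grams) == n)
  if (n > 0) {
    if (any(!is.finite(start)) || any(!is.finite(grams)) ||
        any(!is.finite(duration))) {
      stop("schedule fields must be finite")
    }
    if (any(grams <= 0)) stop("event grams must be strictly positive")
    if (any(duration <= 0)) stop("event duration must be strictly positive")
  }
  out <- tibble::tibble(start = as.numeric(start),
                        grams = as.numeric(grams),
                        duration = as.numeric(duration))
  out <- dplyr::arrange(out, .data$start)
  if (n > 1) {
    ends <- out$start + out$duration
    if (any(out$start[-1] < ends[-n] - 1e-12)) {
      stop("ingestion events may not overlap")
    }
  }
  class(out) <- c("ogtt_schedule", class(out))
  out
}

#' @rdname ingestion_schedule
#' @param at Start time of the single event (min).
#' @export
bolus_schedule <- function(grams = 50, duration = 0.5, at = 0) {
  ingestion_schedule(at, grams, duration)
}

#' @rdname ingestion_schedule
#' @export
continuous_schedule <- function(grams = 50, duration = 120, at = 0) {
  ingestion_schedule(at, grams, duration)
}

#' Total grams delivered by a schedule
#' @param schedule An [ingestion_schedule()].
#' @return Numeric scalar.
#' @export
total_grams <- function(schedule) {
  stopifnot(inherits(schedule, "ogtt_schedule"))
  sum(schedule$grams)
}

#' Ingestion flux of a schedule at given times
#'
#' Piecewise constant: `grams / duration` g/min inside an event window
#' `[start, start + duration)`, zero elsewhere; its integral over time equals
#' the total ingested grams.
#'
#' @param schedule An [ingestion_schedule()].
#' @param t Numeric vector of times (min).
#' @return Numeric vector of fluxes (g/min), one per element of `t`.
#' @examples
#' ingestion_flux(bolus_schedule(50), 0.25)        # 100
#' ingestion_flux(continuous_schedule(75, 120), 60) # 0.625
#' ingestion_flux(bolus_schedule(50), 10)           # 0
#' @export
ingestion_flux <- function(schedule, t) {
  stopifnot(inherits(schedule, "ogtt_schedule"), all(is.finite(t)))
  vapply(t, function(ti) {
    hit <- ti >= schedule$start & ti < schedule$start + schedule$duration
    if (any(hit)) schedule$grams[hit][1] / schedule$duration[hit][1] else 0
  }, numeric(1))
}

# 3-column matrix (start, end, rate) for the compiled core
schedule_events <- function(schedule) {
  stopifnot(inherits(schedule, "ogtt_schedule"))
  cbind(start = schedule$start,
        end = schedule$start + schedule$duration,
        rate = schedule$grams / schedule$duration)
}

#' Construct an integer ingestion pattern on a slot grid
#'
#' A pattern assigns a nonnegative integer number of grams to each slot of a
#' time grid (by default every 5 min over 0--60 min, 13 slots). The first
#' slot must hold at least 1 g (ingestion starts at time zero).
#'
#' @param grams Integer vector of grams per slot.
#' @param slots Numeric vector of slot times (min); default `seq(0, 60, 5)`.
#' @return An integer vector of class `ogtt_pattern` named by slot time,
#'   with attribute `slots`.
#' @examples
#' ingestion_pattern(c(50, rep(0, 12)))             # 50-g bolus pattern
#' ingestion_pattern(c(1, rep(0, 11), 49))          # endpoint split
#' @export
ingestion_pattern <- function(grams, slots = seq(0, 60, by = 5)) {
  stopifnot(length(grams) == length(slots))
  if (any(!is.finite(grams)) || any(grams < 0) ||
      any(abs(grams - round(grams)) > 1e-9)) {
    stop("pattern doses must be nonnegative integers")
  }
  grams <- as.integer(round(grams))
  if (grams[1] < 1) stop("at least 1 g must be ingested at the first slot")
  structure(stats::setNames(grams, slots), slots = as.numeric(slots),
            class = "ogtt_pattern")
}

#' Convert an ingestion pattern to an explicit schedule
#'
#' Each nonzero slot becomes one event of `event_duration` minutes (default
#' 0.5 min, the bolus convention), with flux `u_s / 0.5` g/min.
#'
#' @param pattern An [ingestion_pattern()].
#' @param event_duration Duration of each slot's event (min).
#' @return An [ingestion_schedule()] with the same total grams.
#' @export
pattern_to_schedule <- function(pattern, event_duration = 0.5) {
  stopifnot(inherits(pattern, "ogtt_pattern"))
  slots <- attr(pattern, "slots")
  keep <- pattern > 0
  ingestion_schedule(slots[keep], as.numeric(pattern[keep]), event_duration)
}
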