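#' Detect maximal runs of continuous flight
#'
#' Scans a score stream for maximal runs of consecutive samples scoring at
#' least `min_qualifying_score` (default 4, the continuous-flapping scores)
#' and keeps runs of at least `min_run_samples` samples (default 7, i.e.
#' 35 min — the smallest run strictly longer than 30 minutes). A single
#' sub-threshold or missing sample terminates a run; shorter runs are
#' discarded. Runs are deliberately *not* hourly-binned: detection must not
#' depend on arbitrary hour boundaries.
#'
#' @param series an [activity_series].
#' @param config a [detection_config()].
#' @return `data.frame` with one row per run: `start`, `end` (sample
#'   indices into `series`, inclusive) and `n_qualifying = end - start + 1`.
#' @export
detect_flight_runs <- function(series, config = detection_config()) {
  stopifnot(inherits(series, "activity_series"),
            inherits(config, "detection_config"))
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_qualifying = integer(0))
  if (nrow(series) == 0L) return(empty)
  q <- !is.na(series$score) & series$score >= config$min_qualifying_score
  r <- rle(q)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= config$min_run_samples
  if (!any(keep)) return(empty)
  data.frame(start = starts[keep], end = ends[keep],
             n_qualifying = r$lengths[keep])
}

#' Aggregate flight runs into per-night flights
#'
#' Attributes each run to the night window containing its first qualifying
#' sample (see [night_window_for()]) and merges all runs of one night into a
#' single night flight: two flight periods during one night are two parts of
#' one flight. Flight duration is the summed qualifying samples across parts
#' (5-minute quanta), departure is the first sample of the first part.
#'
#' @param runs output of [detect_flight_runs()] on the same series.
#' @param series the [activity_series] the runs index into.
#' @param config a [detection_config()] (carried for provenance).
#' @param reference_longitude longitude defining the night windows; default
#'   the breeding-site longitude 12.33 E used when the position is unknown.
#' @param sunrise_utc optional `data.frame(night, sunrise)` (Date, POSIXct):
#'   when supplied, flights ending after their night's sunrise are flagged
#'   `prolonged` (annotation only; durations are unchanged).
#' @return `data.frame` of class `flight_set`, one row per night with at
#'   least one run: `bird_id`, `night`, `departure`, `end`, `n_parts`,
#'   `duration_h`, `prolonged`.
#' @export
nightly_flights <- function(runs, series, config = detection_config(),
                            reference_longitude = 12.33,
                            sunrise_utc = NULL) {
  stopifnot(inherits(series, "activity_series"))
  if (nrow(runs) == 0L) {
    out <- data.frame(bird_id = character(0),
                      night = as.Date(character(0)),
                      departure = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC"),
                      n_parts = integer(0), duration_h = numeric(0),
                      prolonged = logical(0))
    class(out) <- c("flight_set", "data.frame")
    return(out)
  }
  key <- night_key_dates(series$time[runs$start], reference_longitude)
  o <- order(key, runs$start)
  runs <- runs[o, , drop = FALSE]
  key <- key[o]
  grp <- cumsum(!duplicated(key))
  first <- !duplicated(grp)
  last <- !duplicated(grp, fromLast = TRUE)
  out <- data.frame(
    bird_id = bird_id(series),
    night = key[first],
    departure = series$time[runs$start[first]],
    end = series$time[runs$end[last]] + .SAMPLE_SEC,
    n_parts = as.integer(tabulate(grp)),
    duration_h = as.numeric(tapply(runs$n_qualifying, grp, sum)) * 5 / 60,
    prolonged = FALSE
  )
  if (!is.null(sunrise_utc)) {
    m <- match(out$night, sunrise_utc$night)
    out$prolonged <- !is.na(m) & out$end > sunrise_utc$sunrise[m]
  }
  rownames(out) <- NULL
  class(out) <- c("flight_set", "data.frame")
  out
}

#' Detect night flights in an activity series
#'
#' Convenience wrapper: [detect_flight_runs()] followed by
#' [nightly_flights()].
#'
#' @inheritParams nightly_flights
#' @return a `flight_set`; see [nightly_flights()].
#' @examples
#' cohort <- simulate_cohort(1, seed = 7)
#' detect_flights(cohort[[1]]$series)
#' @export
detect_flights <- function(series, config = detection_config(),
                           reference_longitude = 12.33, sunrise_utc = NULL) {
  nightly_flights(detect_flight_runs(series, config), series, config,
                  reference_longitude, sunrise_utc)
}

#' @export
print.flight_set <- function(x, ...) {
  cat(sprintf("<flight_set> %d night flights, %.1f flight hours total\n",
              nrow(x), sum(x$duration_h)))
  NextMethod()
}
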