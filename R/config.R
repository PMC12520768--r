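#' Flight-detection configuration
#'
#' A migratory flight bout is a maximal run of consecutive samples scoring at
#' least `min_qualifying_score`, kept only if it holds at least
#' `min_run_samples` samples. The defaults implement the published rule
#' "periods longer than 30 min with continuous flight": 7 x 5 min = 35 min is
#' the smallest run strictly exceeding 30 minutes.
#'
#' @param min_qualifying_score lowest score counted as flight (default 4).
#' @param min_run_samples minimum consecutive qualifying samples (default 7).
#' @param min_flight_minutes duration a run must strictly exceed (default 30);
#'   kept as the documented contract that `min_run_samples` must satisfy.
#' @return list of class `detection_config`.
#' @export
detection_config <- function(min_qualifying_score = 4L,
                             min_run_samples = 7L,
                             min_flight_minutes = 30) {
  min_qualifying_score <- as.integer(min_qualifying_score)
  min_run_samples <- as.integer(min_run_samples)
  if (min_qualifying_score < 1L || min_qualifying_score > 5L)
    stop("min_qualifying_score must be in 1..5", call. = FALSE)
  if (min_run_samples < 1L) stop("min_run_samples must be >= 1", call. = FALSE)
  if (min_run_samples * 5 <= min_flight_minutes)
    stop("min_run_samples x 5 min must exceed min_flight_minutes", call. = FALSE)
  structure(list(min_qualifying_score = min_qualifying_score,
                 min_run_samples = min_run_samples,
                 min_flight_minutes = min_flight_minutes),
            class = "detection_config")
}

#' Segmentation configuration
#'
#' Controls how detected night flights are clustered into migratory flight
#' segments. Clusters split at inter-night gaps strictly greater than
#' `gap_threshold_days` (the ">9 day stopover" rule). Clusters with fewer
#' than `min_segment_nights` flight nights are set aside as odd flights.
#' Within spring, the last two segments are separated by the Zugknick rule:
#' the first night whose departure is more than `zugknick_delay_h` hours
#' later than the baseline departure time (median of the first
#' `zugknick_baseline_nights` nights after the longest spring stopover)
#' starts the final segment.
#'
#' @param gap_threshold_days stopover gap splitting clusters (default 9).
#' @param zugknick_delay_h departure delay starting the last segment
#'   (default 1.5 h).
#' @param zugknick_baseline_nights nights defining the baseline departure
#'   time (default 2).
#' @param min_segment_nights minimum flight nights for a cluster to count as
#'   a segment rather than odd flights (default 3).
#' @param expected_autumn_segments autumn segment count that does not trigger
#'   a diagnostic warning (default 3).
#' @return list of class `segmentation_config`.
#' @export
segmentation_config <- function(gap_threshold_days = 9,
                                zugknick_delay_h = 1.5,
                                zugknick_baseline_nights = 2L,
                                min_segment_nights = 3L,
                                expected_autumn_segments = 3L) {
  if (gap_threshold_days <= 0) stop("gap_threshold_days must be > 0", call. = FALSE)
  if (zugknick_delay_h <= 0) stop("zugknick_delay_h must be > 0", call. = FALSE)
  if (min_segment_nights < 1L) stop("min_segment_nights must be >= 1", call. = FALSE)
  structure(list(gap_threshold_days = gap_threshold_days,
                 zugknick_delay_h = zugknick_delay_h,
                 zugknick_baseline_nights = as.integer(zugknick_baseline_nights),
                 min_segment_nights = as.integer(min_segment_nights),
                 expected_autumn_segments = as.integer(expected_autumn_segments)),
            class = "segmentation_config")
}

# Default per-segment itinerary parameters. Phenology, flight counts,
# per-flight durations and maxima follow the cohort descriptives of the
# red-backed shrike study system (mean +/- s.d. per segment); waypoints are a
# plausible loop Denmark -> SE Europe -> Sahel -> SW Africa -> Horn of
# Africa -> Middle East -> Denmark. Segment 6 starts from a waypoint well
# west of segment 5's endpoint: the westward course change (Zugknick) into
# Europe is planted as a longitude shift so that the departure-time delay it
# causes is an emergent solar-geometry signal.
default_segment_params <- function() {
  data.frame(
    segment_id = 1:6,
    season = c("autumn", "autumn", "autumn", "spring", "spring", "spring"),
    start_mmdd = c("07-31", "08-31", "11-01", "03-28", "05-08", "05-19"),
    start_sd_days = c(7.0, 6.2, 9.0, 5.5, 7.6, 4.3),
    n_flights_mean = c(7.8, 9.3, 14.1, 21.2, 8.5, 12.8),
    n_flights_sd = c(2.8, 2.4, 3.3, 4.6, 0.9, 1.8),
    flight_h_mean = c(4.2, 7.2, 6.4, 5.8, 8.7, 5.7),
    flight_h_sd = c(1.7, 3.8, 3.4, 3.2, 2.2, 2.0),
    flight_h_max = c(8.2, 17.2, 11.0, 10.8, 15.4, 8.4),
    total_h_mean = c(32.6, 67.3, 90.3, 121.9, 73.3, 73.0),
    total_h_sd = c(10.0, 9.8, 14.1, 17.7, 6.2, 6.8),
    duration_days_mean = c(12.6, 13.3, 26.4, 34.6, 9.0, 12.8),
    duration_days_sd = c(6.7, 6.4, 11.8, 9.4, 1.3, 2.1),
    lat0 = c(55.98, 45, 14, -22, 10, 38),
    lon0 = c(12.33, 25, 15, 18, 48, 23),
    lat1 = c(45, 14, -22, 10, 35, 55.98),
    lon1 = c(25, 15, 18, 48, 48, 12.33)
  )
}

#' Synthetic annual-itinerary configuration
#'
#' Parameterizes the synthetic-data generator: one annual migration cycle of
#' six flight segments (three autumn, three spring) separated by stopovers,
#' plus isolated "odd" flights inside long stationary periods. Defaults are
#' the study-system cohort values (means +/- s.d.); distributions are normal
#' (dates, counts, stopovers) and truncated normal (per-flight hours), with
#' clamps that keep the planted truth well-posed for the segmentation rules:
#' autumn stopovers >= 10 d (so the >9 d rule always separates segments),
#' Horn-of-Africa stop >= 4 d (always the longest spring gap), segment-5/6
#' stop in 0..3 d, per-segment flight counts >= `min_flights_per_segment`,
#' odd flights >= `odd_min_separation_days` from segments and each other.
#'
#' @param segments per-segment parameter table; see
#'   `migflight:::default_segment_params()` for the column contract.
#' @param stopovers named list of stopover-day means/s.d.s between successive
#'   segments (`se_europe`, `sahel`, `winter`, `horn`, `seg5_6`).
#' @param odd_flights_mean,odd_flights_sd per-bird odd-flight count
#'   distribution.
#' @param odd_flight_h_mean,odd_flight_h_sd,odd_flight_h_max odd-flight
#'   duration distribution (truncated normal on (1, max]).
#' @param odd_min_separation_days minimum isolation of planted odd flights.
#' @param min_flights_per_segment lower clamp on drawn per-segment flight
#'   counts.
#' @param max_intra_gap_days largest night-date difference between successive
#'   flights inside a segment (default 3).
#' @param departure_jitter_min departures are drawn uniformly within this many
#'   minutes after local sunset.
#' @param noise_rate per-sample probability of replacing an emitted score by
#'   a uniform random score 0-5 (default 0: noise-free).
#' @param missing_hour_rate per-hour probability of blanking a whole hour to
#'   missing (default 0).
#' @param prolonged_flights if `TRUE`, one random flight in the
#'   sea/desert-crossing segment per bird is extended up to 3 h past sunrise.
#' @param start_year calendar year in which the cycle starts (1 July).
#' @return list of class `itinerary_config`.
#' @export
itinerary_config <- function(segments = default_segment_params(),
                             stopovers = list(
                               se_europe = c(mean = 18.6, sd = 8.6),
                               sahel     = c(mean = 49.2, sd = 6.8),
                               winter    = c(mean = 120.6, sd = 10.5),
                               horn      = c(mean = 5.8, sd = 3.5),
                               seg5_6    = c(mean = 0.6, sd = 0.9)),
                             odd_flights_mean = 3.3,
                             odd_flights_sd = 2.4,
                             odd_flight_h_mean = 4.4,
                             odd_flight_h_sd = 2.1,
                             odd_flight_h_max = 8,
                             odd_min_separation_days = 10,
                             min_flights_per_segment = 3L,
                             max_intra_gap_days = 3L,
                             departure_jitter_min = 40,
                             noise_rate = 0,
                             missing_hour_rate = 0,
                             prolonged_flights = FALSE,
                             start_year = 2014L) {
  stopifnot(is.data.frame(segments), nrow(segments) == 6L)
  sds <- c(segments$start_sd_days, segments$n_flights_sd, segments$flight_h_sd,
           segments$duration_days_sd, segments$total_h_sd,
           vapply(stopovers, function(s) s[["sd"]], numeric(1)),
           odd_flights_sd, odd_flight_h_sd)
  if (any(sds < 0)) stop("all s.d. values must be >= 0", call. = FALSE)
  if (any(vapply(stopovers, function(s) s[["mean"]], numeric(1)) < 0))
    stop("stopover means must be >= 0", call. = FALSE)
  if (any(segments$flight_h_max < segments$flight_h_mean))
    stop("flight_h_max below flight_h_mean", call. = FALSE)
  if (noise_rate < 0 || noise_rate > 1 || missing_hour_rate < 0 || missing_hour_rate > 1)
    stop("rates must be in [0, 1]", call. = FALSE)
  structure(list(segments = segments, stopovers = stopovers,
                 odd_flights_mean = odd_flights_mean,
                 odd_flights_sd = odd_flights_sd,
                 odd_flight_h_mean = odd_flight_h_mean,
                 odd_flight_h_sd = odd_flight_h_sd,
                 odd_flight_h_max = odd_flight_h_max,
                 odd_min_separation_days = odd_min_separation_days,
                 min_flights_per_segment = as.integer(min_flights_per_segment),
                 max_intra_gap_days = as.integer(max_intra_gap_days),
                 departure_jitter_min = departure_jitter_min,
                 noise_rate = noise_rate,
                 missing_hour_rate = missing_hour_rate,
                 prolonged_flights = isTRUE(prolonged_flights),
                 start_year = as.integer(start_year)),
            class = "itinerary_config")
}
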