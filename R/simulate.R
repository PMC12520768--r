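#' @title Synthetic annual-itinerary generator
#' @name simulate
#' @description
#' Generates annual logger records with planted ground truth: a six-segment
#' loop migration (three autumn, three spring segments) whose phenology,
#' flight counts, per-flight durations and stopover durations follow the
#' study-system cohort descriptives, with nocturnal flights scheduled
#' between local sunset and sunrise along a geographic waypoint path, plus
#' isolated odd flights inside long stationary periods. The planted truth is
#' the oracle against which detection and segmentation are validated.
NULL

# mean of a normal(mu, sd) truncated to (lower, upper]
tn_mean <- function(mu, sd, lower, upper) {
  a <- (lower - mu) / sd
  b <- (upper - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# location parameter such that the (lower, upper]-truncated normal has the
# requested mean: truncation is asymmetric (the observed per-flight maximum
# sits much closer to the mean than the 1 h floor does), so drawing around
# the printed mean directly would bias the realized mean.
tn_location <- function(target, sd, lower, upper) {
  if (sd == 0) return(target)
  stats::uniroot(function(mu) tn_mean(mu, sd, lower, upper) - target,
                 interval = c(target - 4 * sd, target + 4 * sd),
                 tol = 1e-8)$root
}

# truncated-normal draws on (lower, upper] by rejection, moment-matched so
# the realized mean equals `mean`
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  mean <- tn_location(mean, sd, lower, upper)
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower | x > upper)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower | x[bad] > upper]
    guard <- guard + 1L
    if (guard > 10000L)
      stop("rnorm_trunc(): truncation interval has negligible mass", call. = FALSE)
  }
  x
}

# n_gaps inter-night differences in 1..max_gap summing to ~target_span:
# start from all-consecutive nights and spread the extra rest days randomly.
compose_gaps <- function(n_gaps, target_span, max_gap = 3L) {
  if (n_gaps == 0L) return(integer(0))
  target <- round(min(max(target_span, n_gaps), max_gap * n_gaps))
  g <- rep(1L, n_gaps)
  extra <- target - n_gaps
  if (extra > 0L) {
    slots <- rep(seq_len(n_gaps), each = max_gap - 1L)
    add <- sample(slots, extra)
    g <- g + tabulate(add, nbins = n_gaps)
  }
  g
}

.phase_waypoints <- data.frame(
  phase = c("pre-migration", "stopover-SE-Europe", "stopover-Sahel", "winter"),
  lat = c(55.98, 45, 14, -22),
  lon = c(12.33, 25, 15, 18)
)

#' Simulate one bird's annual itinerary (ground truth)
#'
#' Draws an annual migration itinerary: segment 1 starts at a normally
#' distributed date; each later segment starts after the drawn stopover
#' (chained phenology, so stopover and start-date means are reproduced
#' simultaneously). Per-segment flight counts are normal draws rounded and
#' clamped; flight nights inside autumn segments and segment 4 are spaced
#' with gaps of at most `max_intra_gap_days`, while segments 5 and 6 use
#' strictly consecutive nights. Nightly departure positions are interpolated
#' linearly along each segment's waypoint pair; each flight departs shortly
#' after local sunset (uniform jitter), its duration is a truncated-normal
#' draw quantized to the 5-minute grid and truncated to end before local
#' sunrise. Odd flights are planted in up to four phases (pre-migration, the
#' two autumn stopovers, winter), initiated mid-night, and isolated by at
#' least `odd_min_separation_days` from segments and from each other.
#'
#' @param config an [itinerary_config()].
#' @param bird_id character identifier.
#' @param seed integer seed; the draw is fully reproducible.
#' @return list of class `itinerary_truth`: `$flights` (night, departure,
#'   n_samples, duration_h, label "1".."6" or "odd", phase, lat, lon,
#'   prolonged), `$positions` (per-date lat/lon), `$winter_interval`,
#'   `$cycle` (first/last emitted date), `$bird_id`.
#' @export
simulate_itinerary <- function(config = itinerary_config(), bird_id = "bird01",
                               seed = 1L) {
  stopifnot(inherits(config, "itinerary_config"))
  set.seed(seed)
  sg <- config$segments
  yr <- config$start_year
  cycle_start <- as.Date(sprintf("%d-07-01", yr))

  stop_draw <- function(name, min_days, max_days = Inf) {
    p <- config$stopovers[[name]]
    min(max(round(stats::rnorm(1, p[["mean"]], p[["sd"]])), min_days), max_days)
  }

  # --- flight-night calendar, chained through the stopovers -------------
  n_fl <- pmax(config$min_flights_per_segment,
               round(stats::rnorm(6, sg$n_flights_mean, sg$n_flights_sd)))
  seg_nights <- vector("list", 6L)
  seg1_anchor <- as.Date(sprintf("%d-%s", yr, sg$start_mmdd[1]))
  start_k <- seg1_anchor + round(stats::rnorm(1, 0, sg$start_sd_days[1]))
  for (k in 1:6) {
    n <- n_fl[k]
    if (k %in% c(5L, 6L)) {
      gaps <- rep(1L, n - 1L)           # consecutive nights
    } else {
      span <- stats::rnorm(1, sg$duration_days_mean[k], sg$duration_days_sd[k])
      gaps <- compose_gaps(n - 1L, span, config$max_intra_gap_days)
    }
    seg_nights[[k]] <- start_k + c(0L, cumsum(gaps))
    last <- seg_nights[[k]][n]
    start_k <- switch(as.character(k),
      "1" = last + stop_draw("se_europe", 10) + 1L,
      "2" = last + stop_draw("sahel", 10) + 1L,
      "3" = last + stop_draw("winter", 60) + 1L,
      "4" = last + stop_draw("horn", 4) + 1L,
      "5" = last + stop_draw("seg5_6", 0, 3) + 1L,
      "6" = last)
  }

  # --- per-flight positions, departures, durations ----------------------
  # per-flight durations are conditioned on a per-segment flight-hour
  # budget: the cohort's segment totals vary far less between birds than
  # independent per-flight draws would produce, so the budget (not the
  # individual flights) is the bird-level random quantity. The truncated
  # normal draw supplies the within-segment *shape* of the durations.
  budget_h <- stats::rnorm(6, sg$total_h_mean, sg$total_h_sd)
  fl <- do.call(rbind, lapply(1:6, function(k) {
    n <- n_fl[k]
    frac <- (seq_len(n) - 1L) / n
    data.frame(night = seg_nights[[k]],
               label = as.character(k),
               phase = NA_character_,
               lat = sg$lat0[k] + frac * (sg$lat1[k] - sg$lat0[k]),
               lon = sg$lon0[k] + frac * (sg$lon1[k] - sg$lon0[k]),
               dur_h = rnorm_trunc(n, sg$flight_h_mean[k], sg$flight_h_sd[k],
                                   1, sg$flight_h_max[k]))
  }))

  sunset <- sun_events(fl$lat, fl$lon, fl$night)$sunset
  sunrise <- sun_events(fl$lat, fl$lon, fl$night + 1L)$sunrise
  dep_raw <- sunset + stats::runif(nrow(fl), 0, config$departure_jitter_min * 60)
  fl$departure <- as.POSIXct(ceiling(as.numeric(dep_raw) / 300) * 300,
                             origin = "1970-01-01", tz = "UTC")
  max_samp <- floor((as.numeric(sunrise) - as.numeric(fl$departure)) / 300)

  # fit the budget under the night-length caps: each flight is capped by
  # min(observed per-flight maximum, available sunset-to-sunrise window);
  # hours clipped on short nights are redistributed to the segment's other
  # nights so that the planted segment total equals the drawn budget
  for (k in 1:6) {
    idx <- which(fl$label == as.character(k))
    cap <- pmin(max_samp[idx] / 12, sg$flight_h_max[k])
    b <- min(max(budget_h[k], 1.1 * length(idx)), 0.98 * sum(cap))
    dur <- fl$dur_h[idx]
    for (it in 1:8) dur <- pmin(pmax(dur * b / sum(dur), 1.02), cap)
    fl$dur_h[idx] <- dur
  }
  fl$n_samples <- as.integer(pmin(round(fl$dur_h * 12), max_samp))
  fl$prolonged <- FALSE

  if (config$prolonged_flights) {
    # one barrier-crossing flight extended a few hours past sunrise
    cand <- which(fl$label == "2")
    i <- cand[sample.int(length(cand), 1L)]
    fl$n_samples[i] <- max_samp[i] + round(stats::runif(1, 0.5, 3) * 12)
    fl$prolonged[i] <- TRUE
  }

  # --- odd flights ------------------------------------------------------
  m <- max(0L, round(stats::rnorm(1, config$odd_flights_mean, config$odd_flights_sd)))
  seg_first <- vapply(seg_nights, function(d) as.numeric(d[1]), numeric(1))
  seg_last <- vapply(seg_nights, function(d) as.numeric(d[length(d)]), numeric(1))
  sep <- config$odd_min_separation_days
  windows <- data.frame(
    phase = .phase_waypoints$phase,
    lo = c(as.numeric(cycle_start) + 1, seg_last[1] + sep,
           seg_last[2] + sep, seg_last[3] + sep),
    hi = c(seg_first[1] - sep, seg_first[2] - sep,
           seg_first[3] - sep, seg_first[4] - sep)
  )
  windows <- windows[windows$hi >= windows$lo, , drop = FALSE]
  odd <- NULL
  if (m > 0L && nrow(windows) > 0L) {
    placed <- numeric(0)
    phases <- character(0)
    for (i in seq_len(m)) {
      for (try in seq_len(200L)) {
        w <- sample.int(nrow(windows), 1L,
                        prob = windows$hi - windows$lo + 1)
        d <- round(stats::runif(1, windows$lo[w], windows$hi[w]))
        if (all(abs(d - placed) >= sep)) {
          placed <- c(placed, d)
          phases <- c(phases, windows$phase[w])
          break
        }
      }
    }
    if (length(placed)) {
      wp <- .phase_waypoints[match(phases, .phase_waypoints$phase), ]
      night <- as.Date(placed, origin = "1970-01-01")
      dur <- rnorm_trunc(length(placed), config$odd_flight_h_mean,
                         config$odd_flight_h_sd, 1, config$odd_flight_h_max)
      s <- sun_events(wp$lat, wp$lon, night)$sunset
      r <- sun_events(wp$lat, wp$lon, night + 1L)$sunrise
      n_samp <- as.integer(round(dur * 12))
      # the flight must fit on the 5-min grid between 30 min after sunset
      # and sunrise (short midsummer nights at the breeding site truncate it)
      lo <- ceiling((as.numeric(s) + 1800) / 300) * 300
      n_samp <- pmin(n_samp, as.integer((as.numeric(r) - lo) %/% 300))
      # initiated mid-night: centre the flight near the middle of the night
      mid <- (lo + as.numeric(r)) / 2
      start_raw <- mid - n_samp * 150 + stats::runif(length(placed), -3600, 3600)
      start_q <- ceiling(start_raw / 300) * 300
      start_q <- pmax(lo, pmin(start_q, (as.numeric(r) - n_samp * 300) %/% 300 * 300))
      odd <- data.frame(night = night, label = "odd", phase = phases,
                        lat = wp$lat, lon = wp$lon, dur_h = dur,
                        departure = as.POSIXct(start_q, origin = "1970-01-01",
                                               tz = "UTC"),
                        n_samples = n_samp, prolonged = FALSE)
    }
  }

  flights <- rbind(fl[, c("night", "departure", "n_samples", "label", "phase",
                          "lat", "lon", "prolonged")],
                   if (!is.null(odd))
                     odd[, c("night", "departure", "n_samples", "label", "phase",
                             "lat", "lon", "prolonged")])
  flights <- flights[order(flights$night), ]
  rownames(flights) <- NULL
  flights$duration_h <- flights$n_samples / 12

  if (any(flights$n_samples < 12 & !flights$prolonged))
    stop("itinerary generation produced a sub-hour flight; config inconsistent",
         call. = FALSE)

  # --- per-date position (last departure position carried forward) ------
  cycle_end <- max(as.Date(sprintf("%d-06-15", yr + 1L)),
                   max(flights$night) + 10L)
  dates <- seq(cycle_start, cycle_end, by = 1L)
  idx <- findInterval(as.numeric(dates), as.numeric(flights$night))
  positions <- data.frame(
    date = dates,
    lat = c(sg$lat0[1], flights$lat)[idx + 1L],
    lon = c(sg$lon0[1], flights$lon)[idx + 1L]
  )

  structure(list(
    bird_id = bird_id,
    flights = flights,
    positions = positions,
    winter_interval = c(start = as.Date(seg_last[3], origin = "1970-01-01"),
                        end = as.Date(seg_first[4], origin = "1970-01-01")),
    cycle = c(start = cycle_start, end = cycle_end),
    n_flights_per_segment = n_fl
  ), class = "itinerary_truth")
}

#' @export
print.itinerary_truth <- function(x, ...) {
  cat(sprintf("<itinerary_truth> %s: %d flights (%d odd), %s .. %s\n",
              x$bird_id, nrow(x$flights), sum(x$flights$label == "odd"),
              format(x$cycle[["start"]]), format(x$cycle[["end"]])))
  invisible(x)
}

#' Emit an activity-score series from a planted itinerary
#'
#' Renders the ground truth as a complete 5-minute score stream: planted
#' flight minutes score 4-5 (continuous flapping), non-flight night samples
#' score 0, and daylight samples score 1-3 following a bimodal diel profile
#' (morning and late-afternoon activity peaks). In the default noise-free
#' mode no non-flight sample ever scores >= 4 and no flight sample scores
#' < 4, so detection can be validated exactly. Optional noise replaces a
#' configured fraction of samples with uniform random scores; optional
#' missing-data mode blanks whole hours.
#'
#' @param truth an `itinerary_truth` from [simulate_itinerary()].
#' @param config the [itinerary_config()] used to generate it.
#' @param seed integer seed for the emission draws.
#' @return an [activity_series] covering the full cycle.
#' @export
emit_activity <- function(truth, config = itinerary_config(), seed = 1L) {
  stopifnot(inherits(truth, "itinerary_truth"))
  set.seed(seed)
  dates <- truth$positions$date
  nd <- length(dates)
  t0 <- as.numeric(dates[1]) * 86400
  time <- as.POSIXct(t0 + (seq_len(nd * 288L) - 1L) * 300,
                     origin = "1970-01-01", tz = "UTC")
  score <- integer(nd * 288L)

  ev <- sun_events(truth$positions$lat, truth$positions$lon, dates)
  day_idx <- rep(seq_len(nd), each = 288L)
  tn <- as.numeric(time)
  is_day <- tn >= as.numeric(ev$sunrise)[day_idx] &
    tn < as.numeric(ev$sunset)[day_idx]

  # diel daytime profile: activity peaks after dawn and before dusk
  u <- (tn[is_day] - as.numeric(ev$sunrise)[day_idx][is_day]) /
    (as.numeric(ev$sunset) - as.numeric(ev$sunrise))[day_idx][is_day]
  pk <- exp(-((u - 0.15) / 0.18)^2) + exp(-((u - 0.85) / 0.18)^2)
  score[is_day] <- 1L + stats::rbinom(sum(is_day), 2L, 0.25 + 0.35 * pmin(pk, 1))

  for (i in seq_len(nrow(truth$flights))) {
    j0 <- (as.numeric(truth$flights$departure[i]) - t0) / 300 + 1
    jj <- seq.int(j0, length.out = truth$flights$n_samples[i])
    jj <- jj[jj >= 1L & jj <= length(score)]
    score[jj] <- sample(4:5, length(jj), replace = TRUE, prob = c(0.15, 0.85))
  }

  if (config$noise_rate > 0) {
    flip <- which(stats::runif(length(score)) < config$noise_rate)
    score[flip] <- sample(0:5, length(flip), replace = TRUE)
  }
  if (config$missing_hour_rate > 0) {
    nh <- length(score) %/% 12L
    blank <- which(stats::runif(nh) < config$missing_hour_rate)
    if (length(blank)) {
      miss <- rep((blank - 1L) * 12L, each = 12L) + seq_len(12L)
      score[miss] <- NA_integer_
    }
  }
  activity_series(time, score, bird_id = truth$bird_id)
}

#' Simulate a cohort of birds
#'
#' Draws `n_birds` independent annual itineraries and their emitted activity
#' series under one configuration. Per-bird seeds are derived from `seed`,
#' so identical `(config, seed)` give byte-identical output.
#'
#' @param n_birds number of birds (default 15, the study cohort size).
#' @param config an [itinerary_config()].
#' @param seed integer master seed.
#' @return list of class `flight_cohort`; each element holds `$truth` and
#'   `$series`.
#' @export
simulate_cohort <- function(n_birds = 15L, config = itinerary_config(),
                            seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_birds)
  out <- lapply(seq_len(n_birds), function(i) {
    truth <- simulate_itinerary(config, sprintf("bird%02d", i),
                                seed = seeds[2L * i - 1L])
    list(truth = truth,
         series = emit_activity(truth, config, seed = seeds[2L * i]))
  })
  names(out) <- vapply(out, function(b) b$truth$bird_id, character(1))
  class(out) <- "flight_cohort"
  out
}

#' @export
print.flight_cohort <- function(x, ...) {
  cat(sprintf("<flight_cohort> %d birds, %d planted flights\n", length(x),
              sum(vapply(x, function(b) nrow(b$truth$flights), numeric(1)))))
  invisible(x)
}
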