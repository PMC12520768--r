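#' Cluster flight nights at stopover gaps
#'
#' Splits an ordered sequence of night flights at every inter-night gap
#' strictly greater than `gap_threshold_days` (the ">9 day stopover" rule:
#' a gap of exactly the threshold does not split). Raising the threshold can
#' only merge clusters, never create new ones.
#'
#' @param flights a `flight_set` (or data.frame with a `night` Date column),
#'   sorted by night.
#' @param config a [segmentation_config()].
#' @return list with `assignment` (integer cluster id per flight, in date
#'   order) and `clusters` (`data.frame`: `cluster_id`, `start_night`,
#'   `end_night`, `n_flights`).
#' @export
cluster_nights <- function(flights, config = segmentation_config()) {
  if (nrow(flights) == 0L)
    return(list(assignment = integer(0),
                clusters = data.frame(cluster_id = integer(0),
                                      start_night = as.Date(character(0)),
                                      end_night = as.Date(character(0)),
                                      n_flights = integer(0))))
  nights <- as.numeric(flights$night)
  if (is.unsorted(nights)) stop("flights must be sorted by night", call. = FALSE)
  assignment <- cumsum(c(1L, diff(nights) > config$gap_threshold_days))
  k <- assignment[length(assignment)]
  first <- !duplicated(assignment)
  last <- !duplicated(assignment, fromLast = TRUE)
  list(assignment = assignment,
       clusters = data.frame(cluster_id = seq_len(k),
                             start_night = flights$night[first],
                             end_night = flights$night[last],
                             n_flights = as.integer(tabulate(assignment))))
}

#' Classify clusters into autumn segments, winter, spring pool and odd flights
#'
#' Clusters with fewer than `min_segment_nights` flights are set aside as odd
#' flights, with a phase assigned from their position relative to the
#' adjacent segments (pre-migration, the two autumn stopovers, winter). The
#' winter interval is the longest gap between consecutive *qualifying*
#' clusters (so mid-winter odd flights cannot bisect it); qualifying
#' clusters before winter become autumn segments 1..k in date order (a
#' diagnostic warning is recorded if k differs from the expected count) and
#' qualifying clusters after winter are pooled for spring processing.
#'
#' @param flights a `flight_set` sorted by night.
#' @param config a [segmentation_config()].
#' @return list: `autumn` (list of flight-index vectors, one per autumn
#'   segment), `spring_pool` (flight indices), `odd` (`data.frame` with
#'   `index`, `phase`), `winter_interval` (Dates), `warnings` (character).
#' @export
classify_annual <- function(flights, config = segmentation_config()) {
  cl <- cluster_nights(flights, config)
  warnings <- character(0)
  qual <- which(cl$clusters$n_flights >= config$min_segment_nights)
  if (length(qual) == 0L)
    stop("no migration detected: no cluster reaches min_segment_nights",
         call. = FALSE)

  qc <- cl$clusters[qual, , drop = FALSE]
  if (nrow(qc) >= 2L) {
    gaps <- as.numeric(qc$start_night[-1L]) - as.numeric(qc$end_night[-nrow(qc)])
    w <- which.max(gaps)
    winter_interval <- c(start = qc$end_night[w], end = qc$start_night[w + 1L])
    autumn_ids <- qc$cluster_id[seq_len(w)]
    spring_ids <- qc$cluster_id[(w + 1L):nrow(qc)]
  } else {
    warnings <- c(warnings, "single qualifying cluster: no winter interval identifiable")
    winter_interval <- c(start = as.Date(NA), end = as.Date(NA))
    autumn_ids <- qc$cluster_id
    spring_ids <- integer(0)
  }
  k <- length(autumn_ids)
  if (k != config$expected_autumn_segments)
    warnings <- c(warnings, sprintf("%d autumn segments found (expected %d)",
                                    k, config$expected_autumn_segments))
  if (length(spring_ids) == 0L)
    warnings <- c(warnings, "no spring flight segments found")

  autumn <- lapply(autumn_ids, function(id) which(cl$assignment == id))
  spring_pool <- which(cl$assignment %in% spring_ids)

  # phase of each odd cluster, from its date relative to the segments
  odd_ids <- setdiff(cl$clusters$cluster_id, qual)
  odd <- data.frame(index = integer(0), phase = character(0))
  if (length(odd_ids)) {
    a_start <- as.numeric(qc$start_night[match(autumn_ids, qc$cluster_id)])
    a_end <- as.numeric(qc$end_night[match(autumn_ids, qc$cluster_id)])
    spring_start <- if (length(spring_ids))
      as.numeric(qc$start_night[match(spring_ids[1L], qc$cluster_id)]) else Inf
    for (id in odd_ids) {
      idx <- which(cl$assignment == id)
      d <- stats::median(as.numeric(flights$night[idx]))
      phase <- if (d < a_start[1L]) {
        "pre-migration"
      } else if (d > a_end[k] && d < spring_start) {
        "winter"
      } else {
        between <- which(d > a_end[-k] & d < a_start[-1L])
        if (length(between) == 1L && k == 3L) {
          c("stopover-SE-Europe", "stopover-Sahel")[between]
        } else if (length(between) == 1L) {
          "autumn-stopover"
        } else {
          warnings <- c(warnings,
                        sprintf("odd flights at %s not attributable to a stationary phase",
                                format(as.Date(d, origin = "1970-01-01"))))
          "other"
        }
      }
      odd <- rbind(odd, data.frame(index = idx, phase = phase))
    }
  }

  list(autumn = autumn, spring_pool = spring_pool, odd = odd,
       winter_interval = winter_interval, warnings = warnings)
}

#' Split spring flights at the longest stopover
#'
#' During spring the first segment is separated from the rest by the longest
#' stopover (not a fixed gap threshold): the boundary falls at the single
#' longest inter-night gap within the pooled spring flights, the earliest
#' such gap on ties. Nights before the boundary form segment 4.
#'
#' @param flights the pooled spring `flight_set` rows, sorted by night
#'   (at least 2 flight nights).
#' @param config a [segmentation_config()].
#' @return list with `segment4` and `remainder` (index vectors into
#'   `flights`).
#' @export
split_spring <- function(flights, config = segmentation_config()) {
  n <- nrow(flights)
  if (n < 2L)
    stop("split_spring() needs at least 2 spring flight nights", call. = FALSE)
  gaps <- diff(as.numeric(flights$night))
  b <- which.max(gaps)            # earliest maximal gap
  list(segment4 = seq_len(b), remainder = (b + 1L):n)
}

#' Separate the last two spring segments by the departure-delay (Zugknick) rule
#'
#' After the longest spring stopover the birds fly on (nearly) consecutive
#' nights; the abrupt westward course change into Europe shows up as a
#' sudden delay in nocturnal departure time (later local sunsets at more
#' westerly longitudes). The baseline is the median departure clock time
#' (UTC) of the first `zugknick_baseline_nights` nights; the first night
#' departing more than `zugknick_delay_h` hours after the baseline starts
#' the final segment, and all later nights belong to it even if their
#' departures recede. If no night crosses the threshold all nights stay in
#' segment 5 and a warning is recorded.
#'
#' @param flights the post-segment-4 spring `flight_set` rows, sorted by
#'   night (at least 3 nights).
#' @param config a [segmentation_config()].
#' @return list with `segment5`, `segment6` (index vectors into `flights`)
#'   and `warnings` (character).
#' @export
zugknick_split <- function(flights, config = segmentation_config()) {
  n <- nrow(flights)
  if (n < 3L)
    stop("zugknick_split() needs at least 3 flight nights", call. = FALSE)
  clock <- as.numeric(flights$departure) %% 86400
  nb <- min(config$zugknick_baseline_nights, n)
  baseline <- stats::median(clock[seq_len(nb)])
  j <- which(clock > baseline + config$zugknick_delay_h * 3600)[1L]
  if (is.na(j))
    return(list(segment5 = seq_len(n), segment6 = integer(0),
                warnings = "no departure-delay shift found: spring not split into segments 5 and 6"))
  list(segment5 = if (j > 1L) seq_len(j - 1L) else integer(0),
       segment6 = j:n, warnings = character(0))
}

summarize_segment <- function(flights, segment_id, season) {
  end_date <- max(as.Date(flights$end, tz = "UTC"))
  start_date <- min(flights$night)
  data.frame(segment_id = segment_id, season = season,
             start_date = start_date, end_date = end_date,
             duration_days = as.numeric(end_date - start_date),
             n_flights = nrow(flights),
             total_flight_h = sum(flights$duration_h),
             mean_flight_h = mean(flights$duration_h),
             max_flight_h = max(flights$duration_h))
}

#' Segment a bird's annual cycle of night flights
#'
#' Full segmentation of one bird-year: clusters night flights at stopover
#' gaps ([cluster_nights()]), separates qualifying segments from odd flights
#' and locates winter ([classify_annual()]), numbers the autumn segments,
#' splits spring at the longest stopover ([split_spring()]) and separates
#' the last two spring segments by the departure-delay rule
#' ([zugknick_split()]). Every detected flight receives exactly one label:
#' a segment number or `"odd"`.
#'
#' @param flights a `flight_set` for one bird (any order; sorted internally).
#' @param config a [segmentation_config()].
#' @return object of class `migration`: `$flights` (the input plus `label`
#'   and `phase` columns), `$segments` (one summary row per segment:
#'   start/end date, duration in days, flight count, total/mean/max flight
#'   hours), `$odd_flights`, `$winter_interval`, `$warnings`.
#' @examples
#' cohort <- simulate_cohort(1, seed = 7)
#' m <- segment_migration(detect_flights(cohort[[1]]$series))
#' m$segments
#' @export
segment_migration <- function(flights, config = segmentation_config()) {
  stopifnot(inherits(flights, "data.frame"))
  flights <- flights[order(flights$night), , drop = FALSE]
  rownames(flights) <- NULL
  ann <- classify_annual(flights, config)
  warnings <- ann$warnings

  label <- rep(NA_character_, nrow(flights))
  phase <- rep(NA_character_, nrow(flights))
  for (i in seq_along(ann$autumn)) label[ann$autumn[[i]]] <- as.character(i)
  if (nrow(ann$odd)) {
    label[ann$odd$index] <- "odd"
    phase[ann$odd$index] <- ann$odd$phase
  }

  sp <- ann$spring_pool
  if (length(sp) >= 2L) {
    s4 <- split_spring(flights[sp, , drop = FALSE], config)
    label[sp[s4$segment4]] <- "4"
    rem <- sp[s4$remainder]
    if (length(rem) >= 3L) {
      zk <- zugknick_split(flights[rem, , drop = FALSE], config)
      warnings <- c(warnings, zk$warnings)
      label[rem[zk$segment5]] <- "5"
      label[rem[zk$segment6]] <- "6"
    } else {
      warnings <- c(warnings,
                    "too few post-segment-4 nights for the departure-delay rule; labelled segment 5")
      label[rem] <- "5"
    }
  } else if (length(sp) == 1L) {
    warnings <- c(warnings, "single spring flight night; labelled segment 4")
    label[sp] <- "4"
  }

  flights$label <- label
  flights$phase <- phase
  class(flights) <- c("flight_set", "data.frame")

  seg_labels <- sort(unique(label[label != "odd" & !is.na(label)]))
  segments <- do.call(rbind, lapply(seg_labels, function(l) {
    summarize_segment(flights[which(label == l), , drop = FALSE],
                      as.integer(l), if (as.integer(l) <= 3L) "autumn" else "spring")
  }))

  structure(list(
    bird_id = flights$bird_id[1L],
    flights = flights,
    segments = segments,
    odd_flights = flights[which(label == "odd"), , drop = FALSE],
    winter_interval = ann$winter_interval,
    warnings = warnings,
    config = config
  ), class = "migration")
}

#' @export
print.migration <- function(x, ...) {
  cat(sprintf("<migration> bird %s: %d flights in %d segments + %d odd\n",
              x$bird_id, nrow(x$flights), nrow(x$segments),
              nrow(x$odd_flights)))
  if (!is.na(x$winter_interval[["start"]]))
    cat(sprintf("  winter: %s .. %s\n", format(x$winter_interval[["start"]]),
                format(x$winter_interval[["end"]])))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
summary.migration <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$segments, row.names = FALSE)
  invisible(object$segments)
}
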