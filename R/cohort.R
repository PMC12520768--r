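#' Run detection and segmentation over a simulated cohort
#'
#' @param cohort a `flight_cohort` from [simulate_cohort()].
#' @param detection a [detection_config()].
#' @param segmentation a [segmentation_config()].
#' @param reference_longitude night-window longitude passed to
#'   [detect_flights()].
#' @return named list of `migration` objects, one per bird.
#' @export
process_cohort <- function(cohort,
                           detection = detection_config(),
                           segmentation = segmentation_config(),
                           reference_longitude = 12.33) {
  stopifnot(inherits(cohort, "flight_cohort"))
  lapply(cohort, function(bird) {
    segment_migration(
      detect_flights(bird$series, detection, reference_longitude),
      segmentation)
  })
}

cell_stats <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  c(mean = if (n) mean(values) else NA_real_,
    sd = if (n >= 2L) stats::sd(values) else NA_real_,
    n = n)
}

#' Cohort summary table of the annual migratory flight activity
#'
#' Per-segment and per-season descriptives across birds, in the layout of
#' the study's cohort table: start and end dates, number of flights,
#' segment duration (days), total flight hours (each as mean, sample s.d.
#' and its own n of birds with data for that cell), per-flight duration
#' pooled across all flights (mean, s.d., max), and coefficients of
#' variation. Season rows pool segments 1-3 (autumn) and 4-6 (spring):
#' counts and hours are per-bird sums, the season duration runs from the
#' first to the last flight of the season. Odd flights are excluded
#' throughout (see [odd_summary()]).
#'
#' @param migrations list of `migration` objects (one per bird).
#' @return `data.frame` of class `cohort_table`, one row per segment 1-6
#'   plus `autumn` and `spring`.
#' @export
cohort_table <- function(migrations) {
  stopifnot(length(migrations) >= 1L)
  units <- list("1" = "1", "2" = "2", "3" = "3", "4" = "4", "5" = "5",
                "6" = "6", autumn = c("1", "2", "3"),
                spring = c("4", "5", "6"))
  rows <- lapply(names(units), function(u) {
    labs <- units[[u]]
    per_bird <- lapply(migrations, function(m) {
      seg <- m$segments[m$segments$segment_id %in% as.integer(labs), , drop = FALSE]
      if (nrow(seg) == 0L) return(NULL)
      fl <- m$flights[m$flights$label %in% labs, , drop = FALSE]
      data.frame(start = min(seg$start_date), end = max(seg$end_date),
                 n_flights = sum(seg$n_flights),
                 duration_days = as.numeric(max(seg$end_date) - min(seg$start_date)),
                 total_h = sum(seg$total_flight_h),
                 flight_h = I(list(fl$duration_h)))
    })
    per_bird <- per_bird[!vapply(per_bird, is.null, logical(1))]
    if (length(per_bird) == 0L)
      return(NULL)
    pb <- do.call(rbind, per_bird)
    all_fl <- unlist(pb$flight_h)
    st <- cell_stats(as.numeric(pb$start))
    en <- cell_stats(as.numeric(pb$end))
    nf <- cell_stats(pb$n_flights)
    du <- cell_stats(pb$duration_days)
    th <- cell_stats(pb$total_h)
    data.frame(
      segment = u,
      start_date_mean = as.Date(round(st[["mean"]]), origin = "1970-01-01"),
      start_date_sd = st[["sd"]], start_n = st[["n"]],
      end_date_mean = as.Date(round(en[["mean"]]), origin = "1970-01-01"),
      end_date_sd = en[["sd"]], end_n = en[["n"]],
      n_flights_mean = nf[["mean"]], n_flights_sd = nf[["sd"]],
      n_flights_n = nf[["n"]],
      duration_days_mean = du[["mean"]], duration_days_sd = du[["sd"]],
      duration_days_n = du[["n"]],
      total_flight_h_mean = th[["mean"]], total_flight_h_sd = th[["sd"]],
      total_flight_h_n = th[["n"]],
      per_flight_h_mean = mean(all_fl),
      per_flight_h_sd = if (length(all_fl) >= 2L) stats::sd(all_fl) else NA_real_,
      per_flight_h_max = max(all_fl),
      cv_n_flights = if (is.na(nf[["sd"]])) NA_real_ else
        cv_percent(nf[["mean"]], nf[["sd"]]),
      cv_duration_days = if (is.na(du[["sd"]])) NA_real_ else
        cv_percent(du[["mean"]], du[["sd"]]),
      cv_total_flight_h = if (is.na(th[["sd"]])) NA_real_ else
        cv_percent(th[["mean"]], th[["sd"]])
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' @export
print.cohort_table <- function(x, ...) {
  fmt <- function(m, s, n) {
    ifelse(is.na(s), sprintf("%.1f/%d", m, n),
           sprintf("%.1f ± %.1f/%d", m, s, n))
  }
  disp <- data.frame(
    segment = x$segment,
    start = paste0(format(x$start_date_mean, "%d %b"), " ± ",
                   formatC(x$start_date_sd, digits = 1, format = "f")),
    end = paste0(format(x$end_date_mean, "%d %b"), " ± ",
                 formatC(x$end_date_sd, digits = 1, format = "f")),
    n_flights = fmt(x$n_flights_mean, x$n_flights_sd, x$n_flights_n),
    duration_d = fmt(x$duration_days_mean, x$duration_days_sd, x$duration_days_n),
    total_h = fmt(x$total_flight_h_mean, x$total_flight_h_sd, x$total_flight_h_n),
    per_flight_h = sprintf("%.1f ± %.1f max %.1f", x$per_flight_h_mean,
                           x$per_flight_h_sd, x$per_flight_h_max)
  )
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Summary of odd flights across a cohort
#'
#' Odd flights (isolated night flights inside long stationary periods) are
#' excluded from the segment statistics; this reports them separately:
#' per-bird counts and hours, pooled mean flight duration, and their share
#' of the annual flight activity.
#'
#' @param migrations list of `migration` objects.
#' @return one-row `data.frame`: mean/s.d. of per-bird odd-flight count and
#'   hours, pooled mean odd-flight duration, and percentage of total annual
#'   flight hours and flight count.
#' @export
odd_summary <- function(migrations) {
  per_bird <- do.call(rbind, lapply(migrations, function(m) {
    data.frame(n_odd = nrow(m$odd_flights),
               odd_h = sum(m$odd_flights$duration_h),
               total_n = nrow(m$flights),
               total_h = sum(m$flights$duration_h))
  }))
  odd_durs <- unlist(lapply(migrations, function(m) m$odd_flights$duration_h))
  data.frame(
    n_odd_mean = mean(per_bird$n_odd),
    n_odd_sd = stats::sd(per_bird$n_odd),
    odd_h_mean = mean(per_bird$odd_h),
    odd_h_sd = stats::sd(per_bird$odd_h),
    odd_flight_h_mean = if (length(odd_durs)) mean(odd_durs) else NA_real_,
    pct_of_total_hours = 100 * mean(per_bird$odd_h) / mean(per_bird$total_h),
    pct_of_total_flights = 100 * mean(per_bird$n_odd) / mean(per_bird$total_n)
  )
}
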