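#' @title Activity-score time series and night-window conventions
#' @name series
#' @description
#' An `activity_series` is one bird's annual accelerometer record: a regular
#' 5-minute grid of integer activity scores 0-5 (count of active accelerometer
#' subsamples per sample; 4-5 indicates sustained flapping flight). Gaps are
#' carried in-band as `NA` scores on the grid, never as absent rows, so hourly
#' data completeness remains computable. All timestamps are UTC.
NULL

.SAMPLE_SEC <- 300L

#' Construct an activity series
#'
#' @param time `POSIXct` (UTC) timestamps, strictly increasing, aligned to the
#'   5-minute grid with constant 5-minute spacing.
#' @param score integer scores in 0-5, `NA` for missing samples.
#' @param bird_id single character identifier.
#' @return A `data.frame` of class `activity_series` with columns `time` and
#'   `score` and attribute `bird_id`.
#' @export
activity_series <- function(time, score, bird_id = "bird") {
  if (!inherits(time, "POSIXct")) stop("`time` must be POSIXct (UTC)", call. = FALSE)
  attr(time, "tzone") <- "UTC"
  secs <- as.numeric(time)
  if (any(secs %% .SAMPLE_SEC != 0))
    stop("timestamps must be aligned to the 5-minute grid", call. = FALSE)
  if (length(time) > 1L && !all(diff(secs) == .SAMPLE_SEC))
    stop("timestamps must be consecutive 5-minute samples (represent gaps as NA scores)",
         call. = FALSE)
  score <- as.integer(score)
  bad <- !is.na(score) & (score < 0L | score > 5L)
  if (any(bad))
    stop("scores must be integers in 0..5 or NA", call. = FALSE)
  if (length(score) != length(time)) stop("time/score length mismatch", call. = FALSE)
  out <- data.frame(time = time, score = score)
  attr(out, "bird_id") <- as.character(bird_id)[1L]
  class(out) <- c("activity_series", "data.frame")
  out
}

#' @export
print.activity_series <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<activity_series> bird %s: %d samples (%.1f days), %d missing\n",
              bird_id(x), n, n / 288, sum(is.na(x$score))))
  if (n > 0L)
    cat(sprintf("  %s .. %s UTC\n", format(x$time[1L]), format(x$time[n])))
  invisible(x)
}

#' Bird identifier of a pipeline object
#' @param x an `activity_series` or other object carrying a `bird_id` attribute.
#' @return character scalar.
#' @export
bird_id <- function(x) attr(x, "bird_id", exact = TRUE)

#' Score one accelerometer sample from its subsamples
#'
#' Each 5-minute sample consists of five short accelerometer subsamples; the
#' sample's activity score is the number of subsamples that detected motion
#' (acceleration varying by more than a quarter g), giving the 0-5 scale used
#' throughout: 0 = no activity, 5 = all subsamples active (continuous
#' flapping flight scores 4-5).
#'
#' @param subsample_active logical vector of exactly 5 subsample outcomes.
#' @return integer score 0-5.
#' @examples
#' score_sample(c(TRUE, TRUE, TRUE, TRUE, TRUE)) # 5
#' score_sample(c(TRUE, FALSE, TRUE, FALSE, FALSE)) # 2
#' @export
score_sample <- function(subsample_active) {
  if (!is.logical(subsample_active) || length(subsample_active) != 5L ||
      anyNA(subsample_active))
    stop("score_sample() expects exactly 5 non-missing logicals", call. = FALSE)
  sum(subsample_active)
}

#' Night window for a calendar date
#'
#' Nocturnal flights span midnight, so flights are attributed to "nights"
#' rather than civil dates. The night keyed by date *d* is the 24-hour window
#' from local solar noon of *d* (12:00 UTC minus longitude/15 h) to the next
#' local solar noon: every flight departing after sunset of *d* and ending
#' before the following sunrise falls inside it.
#'
#' @param date calendar date (`Date` or coercible) of the evening.
#' @param reference_longitude degrees east, in \[-180, 180\]; defaults to the
#'   Danish breeding-site longitude used for real loggers of unknown position.
#' @return list of class `night_window` with `key_date`, `start`, `end`
#'   (POSIXct UTC) and `reference_longitude`.
#' @examples
#' night_window_for(as.Date("2014-08-01"), 15) # starts 11:00 UTC
#' @export
night_window_for <- function(date, reference_longitude = 12.33) {
  date <- as.Date(date)
  if (length(date) != 1L || is.na(date)) stop("`date` must be one date", call. = FALSE)
  lon <- reference_longitude
  if (!is.numeric(lon) || length(lon) != 1L || is.na(lon) || abs(lon) > 180)
    stop("`reference_longitude` must be one number in [-180, 180]", call. = FALSE)
  start <- as.POSIXct(as.numeric(date) * 86400 + 43200 - lon * 240,
                      origin = "1970-01-01", tz = "UTC")
  structure(
    list(key_date = date, start = start, end = start + 86400,
         reference_longitude = lon),
    class = "night_window"
  )
}

#' @export
print.night_window <- function(x, ...) {
  cat(sprintf("<night_window> %s: %s -> %s UTC (lon %.2fE)\n",
              format(x$key_date), format(x$start), format(x$end),
              x$reference_longitude))
  invisible(x)
}

# Night key date containing each instant: inverse of night_window_for().
# Windows tile time, so this is a plain floor in shifted coordinates.
night_key_dates <- function(time, reference_longitude = 12.33) {
  as.Date(time + reference_longitude * 240 - 43200, tz = "UTC")
}

.ts_fmt <- "%Y-%m-%dT%H:%M:%SZ"

#' Read a logger CSV file
#'
#' Parses the canonical logger exchange format: header
#' `bird_id,timestamp_utc,score`, ISO-8601 UTC timestamps on the 5-minute
#' grid, integer scores 0-5 with missing scores serialized as an empty field.
#' Interior gaps in the timestamp sequence are normalized to in-band missing
#' samples so the returned grid is complete. Malformed rows raise an error
#' naming the offending file line.
#'
#' @param path file path.
#' @return an [activity_series].
#' @seealso [write_logger_csv()]
#' @export
read_logger_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(raw), c("bird_id", "timestamp_utc", "score")))
    stop(sprintf("%s: expected header 'bird_id,timestamp_utc,score'", path),
         call. = FALSE)
  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  if (nrow(raw) == 0L) stop(sprintf("%s: no samples", path), call. = FALSE)

  bird <- unique(raw$bird_id)
  if (length(bird) != 1L)
    stop(sprintf("%s: more than one bird_id in file", path), call. = FALSE)

  time <- as.POSIXct(raw$timestamp_utc, format = .ts_fmt, tz = "UTC")
  bad <- which(is.na(time) | as.numeric(time) %% .SAMPLE_SEC != 0)
  if (length(bad))
    stop(sprintf("%s: line %d: malformed or off-grid timestamp '%s'",
                 path, line[bad[1L]], raw$timestamp_utc[bad[1L]]), call. = FALSE)
  if (is.unsorted(time, strictly = TRUE)) {
    bad <- which(diff(as.numeric(time)) <= 0)[1L] + 1L
    stop(sprintf("%s: line %d: timestamps not strictly increasing", path, line[bad]),
         call. = FALSE)
  }

  sc_chr <- trimws(raw$score)
  bad <- which(sc_chr != "" & !grepl("^[0-5]$", sc_chr))
  if (length(bad))
    stop(sprintf("%s: line %d: score '%s' outside 0..5",
                 path, line[bad[1L]], raw$score[bad[1L]]), call. = FALSE)
  score <- ifelse(sc_chr == "", NA_integer_, as.integer(sc_chr))

  # normalize gaps: complete the 5-minute grid with NA scores
  grid <- seq(time[1L], time[length(time)], by = .SAMPLE_SEC)
  full <- rep(NA_integer_, length(grid))
  full[match(as.numeric(time), as.numeric(grid))] <- score
  activity_series(grid, full, bird_id = bird)
}

#' Write a logger CSV file
#'
#' Canonical serialization (fixed column order, ISO-8601 `Z` timestamps,
#' missing scores as empty fields, `\n` line endings): writing the same
#' series twice produces byte-identical files, and `read_logger_csv()` is its
#' exact inverse.
#'
#' @param series an [activity_series].
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_logger_csv <- function(series, path) {
  stopifnot(inherits(series, "activity_series"))
  ts <- format(series$time, .ts_fmt, tz = "UTC")
  sc <- ifelse(is.na(series$score), "", as.character(series$score))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("bird_id,timestamp_utc,score",
               paste(bird_id(series), ts, sc, sep = ",")),
             con, sep = "\n")
  invisible(path)
}
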