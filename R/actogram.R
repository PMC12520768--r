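#' Build a double-plotted actogram grid
#'
#' Aggregates an activity series into hourly cells for actogram display:
#' per clock hour (UTC plus an optional display offset) the mean of the
#' present scores, and an activity class. A complete hour is `none` (mean
#' 0), `high` (at least `min_run_samples` of its 12 samples score at least
#' `min_qualifying_score` — deliberately the same rule as flight detection,
#' so figure and analysis cannot disagree), otherwise `medium`. Hours with
#' 1-11 missing samples are `incomplete`, fully missing hours `missing`.
#'
#' @param series an [activity_series].
#' @param config a [detection_config()]; supplies the high-activity rule.
#' @param window `Date` vector of length 2 (first and last day); defaults to
#'   the days spanned by the series.
#' @param utc_offset display offset in hours added to UTC before assigning
#'   days and hours (default 0: UTC axis).
#' @return object of class `actogram_grid`: `$dates`, `$mean` and `$class`
#'   (day x 24 matrices), `$utc_offset`.
#' @export
actogram_grid <- function(series, config = detection_config(), window = NULL,
                          utc_offset = 0) {
  stopifnot(inherits(series, "activity_series"))
  local_sec <- as.numeric(series$time) + utc_offset * 3600
  if (is.null(window)) {
    window <- range(as.Date(as.POSIXct(range(local_sec), origin = "1970-01-01",
                                       tz = "UTC")))
  }
  window <- as.Date(window)
  if (anyNA(window) || window[2L] < window[1L])
    stop("empty actogram window", call. = FALSE)
  dates <- seq(window[1L], window[2L], by = 1L)
  nd <- length(dates)
  nh <- nd * 24L

  w0 <- as.numeric(dates[1L]) * 86400
  hr <- floor((local_sec - w0) / 3600) + 1
  inside <- hr >= 1 & hr <= nh
  hr <- hr[inside]
  score <- series$score[inside]
  present <- !is.na(score)

  acc <- function(values, idx) {
    out <- numeric(nh)
    if (length(values)) {
      rs <- rowsum(as.numeric(values), idx)
      out[as.integer(rownames(rs))] <- rs
    }
    out
  }
  n_present <- acc(rep(1, sum(present)), hr[present])
  sum_score <- acc(score[present], hr[present])
  qual <- present & score >= config$min_qualifying_score
  n_qual <- acc(rep(1, sum(qual)), hr[qual])

  mean_score <- ifelse(n_present > 0, sum_score / pmax(n_present, 1), NA_real_)
  cls <- ifelse(n_present == 0, "missing",
         ifelse(n_present < 12, "incomplete",
         ifelse(n_qual >= config$min_run_samples, "high",
         ifelse(mean_score == 0, "none", "medium"))))

  structure(list(
    dates = dates,
    mean = matrix(mean_score, nrow = nd, ncol = 24L, byrow = TRUE),
    class = matrix(cls, nrow = nd, ncol = 24L, byrow = TRUE),
    utc_offset = utc_offset
  ), class = "actogram_grid")
}

#' @export
print.actogram_grid <- function(x, ...) {
  cat(sprintf("<actogram_grid> %d days (%s .. %s), utc_offset %+g h\n",
              length(x$dates), format(x$dates[1L]),
              format(x$dates[length(x$dates)]), x$utc_offset))
  tab <- table(factor(x$class, levels = c("none", "medium", "high",
                                          "incomplete", "missing")))
  cat("  hours:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

# colour code: white = no activity, green ramp = medium activity,
# black = high activity / sustained flight, yellow = incomplete hour,
# red = missing hour
.acto_rgb <- function(cls, mean_score) {
  f <- pmin(pmax(mean_score / 3, 0), 1)
  r <- ifelse(cls == "none", 1,
       ifelse(cls == "medium", 1 - f,
       ifelse(cls == "high", 0,
       ifelse(cls == "incomplete", 1, 0.8))))
  g <- ifelse(cls == "none", 1,
       ifelse(cls == "medium", 1 - 0.5 * f,
       ifelse(cls == "high", 0,
       ifelse(cls == "incomplete", 0.85, 0.1))))
  b <- ifelse(cls == "none", 1,
       ifelse(cls == "medium", 1 - f,
       ifelse(cls == "high", 0,
       ifelse(cls == "incomplete", 0.1, 0.1))))
  list(r = r, g = g, b = b)
}

# rows of 48 cells: day d on the left, day d+1 repeated on the right
acto_double_rows <- function(grid) {
  nd <- length(grid$dates)
  nr <- max(1L, nd - 1L)
  pick <- function(mat, fill) {
    right <- if (nd >= 2L) mat[2:nd, , drop = FALSE] else
      matrix(fill, 1L, 24L)
    cbind(mat[seq_len(nr), , drop = FALSE], right)
  }
  list(cls = pick(grid$class, "missing"), mean = pick(grid$mean, NA_real_))
}

#' Render an actogram raster image
#'
#' Writes the double-plotted actogram as a PNG: one row per pair of
#' consecutive days (48 hourly cells, the second day repeated as the first
#' half of the next row), with the standard colour code (white none, green
#' medium, black high, yellow incomplete, red missing). The output is a
#' deterministic function of the grid.
#'
#' @param grid an [actogram_grid()].
#' @param path output PNG path.
#' @param cell_px edge length of one hourly cell in pixels.
#' @return `path`, invisibly.
#' @export
render_actogram <- function(grid, path, cell_px = 4L) {
  stopifnot(inherits(grid, "actogram_grid"))
  if (length(grid$dates) == 0L) stop("empty actogram grid", call. = FALSE)
  dd <- acto_double_rows(grid)
  col <- .acto_rgb(dd$cls, dd$mean)
  expand <- function(channel) {
    m <- matrix(channel, nrow = nrow(dd$cls), ncol = 48L)
    kronecker(m, matrix(1, cell_px, cell_px))
  }
  arr <- array(c(expand(col$r), expand(col$g), expand(col$b)),
               dim = c(nrow(dd$cls) * cell_px, 48L * cell_px, 3L))
  png::writePNG(arr, path)
  invisible(path)
}

#' Plot an actogram grid
#'
#' @param x an [actogram_grid()].
#' @param ... ignored.
#' @export
plot.actogram_grid <- function(x, ...) {
  dd <- acto_double_rows(x)
  col <- .acto_rgb(dd$cls, dd$mean)
  arr <- array(c(matrix(col$r, nrow(dd$cls), 48L),
                 matrix(col$g, nrow(dd$cls), 48L),
                 matrix(col$b, nrow(dd$cls), 48L)),
               dim = c(nrow(dd$cls), 48L, 3L))
  op <- graphics::par(mar = c(2.5, 2.5, 1.5, 0.5))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(0, 48), ylim = c(nrow(dd$cls), 0),
                 xlab = "", ylab = "", xaxs = "i", yaxs = "i",
                 main = paste("actogram:", format(x$dates[1L]), "..",
                              format(x$dates[length(x$dates)])),
                 cex.main = 0.9, las = 1)
  graphics::rasterImage(arr, 0, nrow(dd$cls), 48, 0, interpolate = FALSE)
  invisible(x)
}
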