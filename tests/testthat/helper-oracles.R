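# Independent oracles, deliberately naive: these re-derive the same
# quantities as the package by direct scans / direct formula evaluation and
# must never share code with the implementation they check.

# plain sample-by-sample scan for qualifying runs (no rle, no vectorization)
brute_force_runs <- function(score, min_score = 4L, min_run = 7L) {
  out <- data.frame(start = integer(0), end = integer(0),
                    n_qualifying = integer(0))
  run_start <- NA_integer_
  for (i in seq_along(score)) {
    ok <- !is.na(score[i]) && score[i] >= min_score
    if (ok && is.na(run_start)) run_start <- i
    if (!ok && !is.na(run_start)) {
      if (i - run_start >= min_run)
        out <- rbind(out, data.frame(start = run_start, end = i - 1L,
                                     n_qualifying = i - run_start))
      run_start <- NA_integer_
    }
  }
  if (!is.na(run_start)) {
    n <- length(score) - run_start + 1L
    if (n >= min_run)
      out <- rbind(out, data.frame(start = run_start,
                                   end = length(score), n_qualifying = n))
  }
  out
}

# direct evaluation of the Levene/Brown-Forsythe statistic:
# W = ((N-k)/(k-1)) * sum_i n_i (Zbar_i - Zbar)^2 / sum_ij (Z_ij - Zbar_i)^2
levene_W_formula <- function(groups, center = "median") {
  cfun <- if (center == "median") median else mean
  z <- lapply(groups, function(x) abs(x - cfun(x)))
  n_i <- lengths(z)
  N <- sum(n_i)
  k <- length(z)
  zbar_i <- vapply(z, mean, numeric(1))
  zbar <- mean(unlist(z))
  num <- sum(n_i * (zbar_i - zbar)^2)
  den <- sum(vapply(seq_len(k), function(i) sum((z[[i]] - zbar_i[i])^2),
                    numeric(1)))
  W <- (N - k) / (k - 1) * num / den
  list(W = W, df1 = k - 1, df2 = N - k,
       p = stats::pf(W, k - 1, N - k, lower.tail = FALSE))
}

# random score stream with optional missing samples, for property tests
random_score_stream <- function(n, p_missing = 0.02) {
  s <- sample(0:5, n, replace = TRUE,
              prob = c(0.35, 0.1, 0.1, 0.1, 0.15, 0.2))
  s[runif(n) < p_missing] <- NA_integer_
  s
}

series_from_scores <- function(scores, start = "2014-08-01 00:00:00",
                               bird = "testbird") {
  t0 <- as.POSIXct(start, tz = "UTC")
  activity_series(t0 + (seq_along(scores) - 1L) * 300L, scores, bird_id = bird)
}

# minimal flight_set for unit tests of the segmentation operations
make_flights <- function(night_days, dep_clock_h = 18, duration_h = 6,
                         bird = "t1", origin = as.Date("2014-07-01")) {
  nights <- origin + night_days
  n <- length(nights)
  dep_clock_h <- rep_len(dep_clock_h, n)
  duration_h <- rep_len(duration_h, n)
  dep <- as.POSIXct(as.numeric(nights) * 86400 + dep_clock_h * 3600,
                    origin = "1970-01-01", tz = "UTC")
  out <- data.frame(bird_id = rep_len(bird, n), night = nights, departure = dep,
                    end = dep + duration_h * 3600,
                    n_parts = rep(1L, n), duration_h = duration_h,
                    prolonged = rep(FALSE, n))
  class(out) <- c("flight_set", "data.frame")
  out
}
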