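test_that("identical config and seed give byte-identical output", {
  c1 <- simulate_cohort(2, seed = 314)
  c2 <- simulate_cohort(2, seed = 314)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_logger_csv(c1[[1]]$series, f1)
  write_logger_csv(c2[[1]]$series, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(c1[[2]]$truth$flights, c2[[2]]$truth$flights)
  expect_false(identical(simulate_cohort(1, seed = 315)[[1]]$truth$flights,
                         c1[[1]]$truth$flights))
})

test_that("planted itineraries reproduce the parameter table across a cohort", {
  cc <- get_default_cohort()
  tr <- lapply(cc$cohort, function(b) b$truth$flights)
  sg <- itinerary_config()$segments
  nb <- length(tr)
  for (k in 1:6) {
    lab <- as.character(k)
    n_k <- vapply(tr, function(f) sum(f$label == lab), numeric(1))
    h_k <- vapply(tr, function(f) sum(f$duration_h[f$label == lab]), numeric(1))
    # cohort means within ~3 standard errors of their target parameters
    expect_lt(abs(mean(n_k) - sg$n_flights_mean[k]),
              3 * sg$n_flights_sd[k] / sqrt(nb) + 0.5)
    expect_lt(abs(mean(h_k) - sg$total_h_mean[k]),
              3 * sg$total_h_sd[k] / sqrt(nb) + 2)
  }
  # segment 1 starts around its anchor date
  s1 <- vapply(tr, function(f) as.numeric(min(f$night[f$label == "1"])), numeric(1))
  anchor <- as.numeric(as.Date("2014-07-31"))
  expect_lt(abs(mean(s1) - anchor), 3 * 7 / sqrt(nb) + 1)
  # Sahel stopover mean near its parameter
  sahel <- vapply(tr, function(f) {
    as.numeric(min(f$night[f$label == "3"]) - max(f$night[f$label == "2"])) - 1
  }, numeric(1))
  expect_lt(abs(mean(sahel) - 49.2), 6)
})

test_that("planted truth is well-posed for the segmentation rules", {
  cc <- get_default_cohort()
  for (b in cc$cohort) {
    f <- b$truth$flights
    seg_nights <- lapply(as.character(1:6), function(l) sort(f$night[f$label == l]))
    # intra-segment gaps never exceed 3 nights in autumn (and segment 4)
    for (k in c(1, 2, 3, 4))
      expect_lte(max(diff(as.numeric(seg_nights[[k]]))), 3)
    # segments 5 and 6 fly on strictly consecutive nights
    for (k in c(5, 6))
      expect_true(all(diff(as.numeric(seg_nights[[k]])) == 1))
    # autumn inter-segment stopovers exceed 9 days
    expect_gt(as.numeric(seg_nights[[2]][1] - max(seg_nights[[1]])), 9)
    expect_gt(as.numeric(seg_nights[[3]][1] - max(seg_nights[[2]])), 9)
    # the Horn-of-Africa stop is the longest gap within spring
    spring <- sort(f$night[f$label %in% c("4", "5", "6")])
    horn_gap <- as.numeric(seg_nights[[5]][1] - max(seg_nights[[4]]))
    expect_identical(max(diff(as.numeric(spring))), horn_gap)
    # odd flights are isolated from segments and from each other
    odd <- f$night[f$label == "odd"]
    if (length(odd)) {
      segn <- as.numeric(f$night[f$label != "odd"])
      expect_true(all(vapply(as.numeric(odd), function(d)
        min(abs(d - segn)), numeric(1)) > 9))
      if (length(odd) > 1)
        expect_true(all(diff(sort(as.numeric(odd))) > 9))
    }
    # flights are nocturnal at their position: depart after local sunset,
    # end by the following sunrise (no prolonged flights by default)
    ss <- sun_events(f$lat, f$lon, f$night)$sunset
    sr <- sun_events(f$lat, f$lon, f$night + 1)$sunrise
    expect_true(all(f$departure > ss))
    expect_true(all(f$departure + f$n_samples * 300 <= sr))
  }
})

test_that("emission renders flights as 4-5 scores and quiet nights as zeros", {
  b <- get_default_cohort()$cohort[[1]]
  ser <- b$series
  tr <- b$truth$flights
  t0 <- as.numeric(ser$time[1])
  for (i in sample(nrow(tr), 5)) {
    j0 <- (as.numeric(tr$departure[i]) - t0) / 300 + 1
    jj <- seq(j0, length.out = tr$n_samples[i])
    expect_true(all(ser$score[jj] >= 4))           # flight samples
    expect_lt(ser$score[j0 - 1], 4)                # run boundary is exact
    expect_lt(ser$score[max(jj) + 1], 4)
  }
  # noise-free mode: qualifying scores appear only inside planted flights
  flight_idx <- unlist(lapply(seq_len(nrow(tr)), function(i) {
    j0 <- (as.numeric(tr$departure[i]) - t0) / 300 + 1
    seq(j0, length.out = tr$n_samples[i])
  }))
  qual <- which(!is.na(ser$score) & ser$score >= 4)
  expect_identical(sort(as.integer(flight_idx)), qual)
  expect_false(anyNA(ser$score))
})

test_that("a 6-hour planted flight emits exactly 72 consecutive qualifying samples", {
  cfg <- itinerary_config()
  truth <- simulate_itinerary(cfg, "b72", seed = 99)
  i <- which(abs(truth$flights$duration_h - 6) < 1.5)[1]
  expect_false(is.na(i)) # a mid-length flight always exists in an annual draw
  expect_identical(truth$flights$n_samples[i],
                   as.integer(round(truth$flights$duration_h[i] * 12)))
  ser <- emit_activity(truth, cfg, seed = 100)
  t0 <- as.numeric(ser$time[1])
  j0 <- (as.numeric(truth$flights$departure[i]) - t0) / 300 + 1
  jj <- seq(j0, length.out = truth$flights$n_samples[i])
  expect_true(all(ser$score[jj] >= 4))
})

test_that("degenerate generator options behave as documented", {
  cfg0 <- itinerary_config(odd_flights_mean = 0, odd_flights_sd = 0)
  truth <- simulate_itinerary(cfg0, "noodd", seed = 5)
  expect_false(any(truth$flights$label == "odd"))

  # noise mode at rate 0 equals the noise-free emission
  cfg <- itinerary_config()
  cfgn <- itinerary_config(noise_rate = 0)
  tr <- simulate_itinerary(cfg, "nz", seed = 6)
  expect_identical(emit_activity(tr, cfg, seed = 7)$score,
                   emit_activity(tr, cfgn, seed = 7)$score)

  # missing-data mode blanks whole hours only
  cfgm <- itinerary_config(missing_hour_rate = 0.1)
  ser <- emit_activity(tr, cfgm, seed = 8)
  na_runs <- rle(is.na(ser$score))
  expect_true(all(na_runs$lengths[na_runs$values] %% 12 == 0))
  expect_gt(sum(is.na(ser$score)), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(itinerary_config(odd_flights_sd = -1), "s.d.")
  expect_error(itinerary_config(noise_rate = 2), "rates")
  sg <- migflight:::default_segment_params()
  sg$flight_h_max[2] <- 5 # below the segment's mean duration
  expect_error(itinerary_config(segments = sg), "flight_h_max")
})
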