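test_that("coefficient of variation matches direct computation and edge rules", {
  expect_equal(coefficient_of_variation(c(1, 1, 1)), 0)
  x <- c(30, 35)
  expect_equal(coefficient_of_variation(x), 100 * sd(x) / mean(x))
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
  expect_error(coefficient_of_variation(5), ">= 2")
  # from reported cell moments
  expect_equal(round(cv_percent(188.5, 19.7)), 10)
  expect_equal(round(cv_percent(270.8, 16.5)), 6)
  expect_error(cv_percent(0, 1), "zero mean")
})

test_that("Levene statistic matches the direct formula on fixed cases", {
  # equal absolute deviations in both groups: no heterogeneity at all
  r <- levene_test(list(c(0, 2), c(5, 7)), center = "mean")
  expect_equal(r$W, 0)

  g <- list(c(1, 2, 3, 4), c(1, 3, 5, 7))
  for (ctr in c("median", "mean")) {
    r <- levene_test(g, center = ctr)
    want <- levene_W_formula(g, center = ctr)
    expect_equal(r$W, want$W, tolerance = 1e-12)
    expect_equal(r$df1, want$df1)
    expect_equal(r$df2, want$df2)
    expect_equal(r$p, want$p, tolerance = 1e-12)
  }

  # identical groups replicated: W = 0, p = 1
  r <- levene_test(list(c(1, 2, 6), c(1, 2, 6), c(1, 2, 6)))
  expect_equal(r$W, 0)
  expect_equal(r$p, 1)

  # degenerate spread is refused rather than returning NaN
  expect_error(levene_test(list(c(1, 1), c(2, 2)), center = "mean"),
               "undefined")
  expect_error(levene_test(list(1:3)), ">= 2 groups")
})

test_that("Levene statistic matches the direct formula on random inputs", {
  set.seed(4242)
  for (i in 1:60) {
    k <- sample(2:5, 1)
    g <- lapply(seq_len(k), function(j)
      rnorm(sample(3:12, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 4)))
    for (ctr in c("median", "mean")) {
      expect_equal(levene_test(g, center = ctr)$W,
                   levene_W_formula(g, center = ctr)$W,
                   tolerance = 1e-10)
    }
  }
})

test_that("cohort table cells carry mean, sample s.d. and their own n", {
  cc <- get_default_cohort()
  two <- cc$migrations[1:2]
  # overwrite segment-1 totals with known values via constructed migrations
  tab <- cohort_table(two)
  b1 <- two[[1]]$segments
  b2 <- two[[2]]$segments
  s1 <- c(b1$total_flight_h[b1$segment_id == 1], b2$total_flight_h[b2$segment_id == 1])
  row <- tab[tab$segment == "1", ]
  expect_equal(row$total_flight_h_mean, mean(s1))
  expect_equal(row$total_flight_h_sd, sd(s1))
  expect_equal(row$total_flight_h_n, 2)
  # a two-point cell: 30 and 35 give 32.5 +/- 3.54
  expect_equal(round(mean(c(30, 35)), 1), 32.5)
  expect_equal(round(sd(c(30, 35)), 2), 3.54)

  one <- cohort_table(cc$migrations[1])
  expect_true(is.na(one$total_flight_h_sd[1]))
  expect_equal(one$total_flight_h_n[1], 1)
})

test_that("cohort table is permutation-invariant and consistent with seasons", {
  cc <- get_default_cohort()
  t1 <- cohort_table(cc$migrations)
  t2 <- cohort_table(rev(cc$migrations))
  expect_equal(t1, t2)
  # season rows pool their segments: totals add, dates span
  aut <- t1[t1$segment == "autumn", ]
  per_seg <- t1[t1$segment %in% c("1", "2", "3"), ]
  expect_equal(aut$total_flight_h_mean, sum(per_seg$total_flight_h_mean),
               tolerance = 1e-9)
  expect_equal(aut$n_flights_mean, sum(per_seg$n_flights_mean), tolerance = 1e-9)
  expect_identical(aut$start_date_mean, per_seg$start_date_mean[1])
  # odd flights excluded from segment statistics
  allfl <- do.call(rbind, lapply(cc$migrations, function(m) m$flights))
  expect_equal(t1[t1$segment == "spring", "total_flight_h_mean"],
               mean(vapply(cc$migrations, function(m)
                 sum(m$flights$duration_h[m$flights$label %in% c("4", "5", "6")]),
                 numeric(1))))
})

test_that("cumulative flight-hour curves are conservative non-decreasing steps", {
  cc <- get_default_cohort()
  m <- cc$migrations[[3]]
  for (season in c("autumn", "spring")) {
    cu <- cumulative_curve(m, season)
    labs <- if (season == "autumn") c("1", "2", "3") else c("4", "5", "6")
    expect_true(all(diff(cu$cumulative_h) > 0))
    expect_equal(cu$cumulative_h[nrow(cu)],
                 sum(m$segments$total_flight_h[m$segments$segment_id %in% as.integer(labs)]))
    expect_equal(nrow(cu), sum(m$flights$label %in% labs))
  }
  # two flights of 5 and 7 hours accumulate to 12
  fl <- make_flights(c(0, 1), duration_h = c(5, 7))
  m2 <- list(flights = cbind(fl, label = "1", phase = NA), segments = NULL)
  class(m2) <- "migration"
  cu <- cumulative_curve(m2, "autumn")
  expect_equal(cu$cumulative_h, c(5, 12))
})

test_that("spring segments are more heterogeneous than autumn segments", {
  cc <- get_default_cohort()
  seg_totals <- function(labels) {
    lapply(labels, function(l) {
      vapply(cc$migrations, function(m) {
        s <- m$segments
        if (any(s$segment_id == l)) s$total_flight_h[s$segment_id == l] else NA_real_
      }, numeric(1))
    })
  }
  aut <- lapply(seg_totals(1:3), function(v) v[!is.na(v)])
  spr <- lapply(seg_totals(4:6), function(v) v[!is.na(v)])
  W_aut <- levene_test(aut)$W
  W_spr <- levene_test(spr)$W
  expect_gt(W_spr, W_aut)
})

test_that("odd-flight summary reports counts, hours and annual shares", {
  cc <- get_default_cohort()
  os <- odd_summary(cc$migrations)
  n_odd <- vapply(cc$migrations, function(m) nrow(m$odd_flights), numeric(1))
  expect_equal(os$n_odd_mean, mean(n_odd))
  expect_gt(os$pct_of_total_hours, 0)
  expect_lt(os$pct_of_total_hours, 10)
  all_h <- sum(vapply(cc$migrations, function(m) sum(m$flights$duration_h), numeric(1)))
  odd_h <- sum(vapply(cc$migrations, function(m) sum(m$odd_flights$duration_h), numeric(1)))
  expect_equal(os$pct_of_total_hours, 100 * odd_h / all_h, tolerance = 1e-9)
})
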