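test_that("night clustering splits at gaps strictly greater than the threshold", {
  cl <- cluster_nights(make_flights(c(0, 1, 3, 5, 20, 21)))
  expect_equal(nrow(cl$clusters), 2)
  expect_equal(cl$assignment, c(1, 1, 1, 1, 2, 2))
  expect_identical(cl$clusters$end_night[1], as.Date("2014-07-01") + 5)

  # a gap of exactly 9 days does not split
  cl <- cluster_nights(make_flights(c(0, 9, 18)))
  expect_equal(nrow(cl$clusters), 1)
  cl <- cluster_nights(make_flights(c(0, 10)))
  expect_equal(nrow(cl$clusters), 2)

  # degenerate inputs
  expect_equal(nrow(cluster_nights(make_flights(5))$clusters), 1)
  expect_equal(length(cluster_nights(make_flights(integer(0)))$assignment), 0)
})

test_that("raising the gap threshold never increases the number of clusters", {
  set.seed(202)
  for (i in 1:40) {
    nights <- sort(sample(0:300, sample(5:60, 1)))
    fl <- make_flights(unique(nights))
    ks <- vapply(c(2, 5, 9, 15, 30), function(g) {
      nrow(cluster_nights(fl, segmentation_config(gap_threshold_days = g))$clusters)
    }, numeric(1))
    expect_true(all(diff(ks) <= 0))
  }
})

test_that("annual classification separates autumn segments, winter and odd flights", {
  # 3 autumn clusters + 1 spring cluster around a 120-day winter gap
  nights <- c(0:7, 30:42, 75:90, 210:245)
  ann <- classify_annual(make_flights(nights))
  expect_length(ann$autumn, 3)
  expect_length(ann$spring_pool, 36)
  expect_equal(nrow(ann$odd), 0)
  expect_length(ann$warnings, 0)
  expect_identical(unname(ann$winter_interval["start"]),
                   as.Date("2014-07-01") + 90)
  expect_identical(unname(ann$winter_interval["end"]),
                   as.Date("2014-07-01") + 210)

  # an isolated night 15 days into the Sahel stopover is an odd flight
  ann <- classify_annual(make_flights(sort(c(nights, 57))))
  expect_equal(ann$odd$phase, "stopover-Sahel")
  # and one in the middle of winter
  ann <- classify_annual(make_flights(sort(c(nights, 140))))
  expect_equal(ann$odd$phase, "winter")
  # and one before migration begins
  ann <- classify_annual(make_flights(sort(c(nights + 40, 5))))
  expect_equal(ann$odd$phase, "pre-migration")

  expect_error(classify_annual(make_flights(c(0, 20, 40))), "no migration")
})

test_that("spring splits at the longest stopover, earliest on ties", {
  # gaps 1,1,2,6,1,1: boundary after the 6-day gap
  nights <- cumsum(c(0, 1, 1, 2, 6, 1, 1))
  sp <- split_spring(make_flights(nights))
  expect_equal(sp$segment4, 1:4)
  expect_equal(sp$remainder, 5:7)

  # two equal longest gaps: the earliest is chosen
  nights <- cumsum(c(0, 1, 5, 1, 5, 1))
  sp <- split_spring(make_flights(nights))
  expect_equal(sp$segment4, 1:2)

  expect_error(split_spring(make_flights(3)), "at least 2")
})

test_that("the departure-delay rule starts segment 6 at the first delayed night", {
  dep <- c(17.5, 17 + 40 / 60, 17.75, 19 + 20 / 60, 19 + 25 / 60)
  zk <- zugknick_split(make_flights(0:4, dep_clock_h = dep))
  expect_equal(zk$segment5, 1:3)
  expect_equal(zk$segment6, 4:5)

  # departures within 30 min of each other: no split, with a warning
  zk <- zugknick_split(make_flights(0:4, dep_clock_h = c(17.5, 17.6, 17.7, 17.9, 17.6)))
  expect_equal(zk$segment5, 1:5)
  expect_length(zk$segment6, 0)
  expect_match(zk$warnings, "not split")

  # later nights stay in segment 6 even if departures recede
  zk <- zugknick_split(make_flights(0:4, dep_clock_h = c(17.5, 17.6, 19.5, 17.6, 19.6)))
  expect_equal(zk$segment6, 3:5)

  expect_error(zugknick_split(make_flights(0:1)), "at least 3")
})

test_that("every detected flight receives exactly one label (partition property)", {
  cc <- get_default_cohort()
  for (m in cc$migrations) {
    expect_false(anyNA(m$flights$label))
    expect_equal(sum(m$segments$n_flights) + nrow(m$odd_flights),
                 nrow(m$flights))
    # segments are disjoint in flight nights and ordered in time (a segment
    # whose last flight ends after midnight may share its end *date* with
    # the next segment's first night when no stopover separates them)
    expect_true(all(diff(as.numeric(m$segments$start_date)) > 0))
    expect_true(all(m$segments$start_date[-1] >=
                      m$segments$end_date[-nrow(m$segments)]))
  }
})

test_that("segmentation recovers the planted structure on the default cohort", {
  cc <- get_default_cohort()
  n_aut <- vapply(cc$migrations, function(m) sum(m$segments$season == "autumn"),
                  numeric(1))
  n_spr <- vapply(cc$migrations, function(m) sum(m$segments$season == "spring"),
                  numeric(1))
  expect_equal(as.integer(names(which.max(table(n_aut)))), 3L)
  expect_equal(as.integer(names(which.max(table(n_spr)))), 3L)

  # winter interval equals the planted one
  for (b in names(cc$cohort)) {
    tw <- cc$cohort[[b]]$truth$winter_interval
    dw <- cc$migrations[[b]]$winter_interval
    expect_lte(abs(as.numeric(dw[["start"]] - tw[["start"]])), 1)
    expect_lte(abs(as.numeric(dw[["end"]] - tw[["end"]])), 1)
  }

  # segment-5/6 boundary matches the planted course change for >= 14/15 birds
  hits <- vapply(names(cc$cohort), function(b) {
    tr <- cc$cohort[[b]]$truth$flights
    de <- cc$migrations[[b]]$flights
    t6 <- suppressWarnings(min(tr$night[tr$label == "6"]))
    d6 <- suppressWarnings(min(de$night[de$label == "6"]))
    isTRUE(t6 == d6)
  }, logical(1))
  expect_gte(sum(hits), 14)
})

test_that("odd flights in the planted cohort are classified with their phase", {
  cc <- get_default_cohort()
  cmp <- do.call(rbind, lapply(names(cc$cohort), function(b) {
    tr <- cc$cohort[[b]]$truth$flights
    de <- cc$migrations[[b]]$flights
    merge(data.frame(night = tr$night, tphase = tr$phase, tlab = tr$label),
          data.frame(night = de$night, dphase = de$phase, dlab = de$label))
  }))
  odd <- cmp[cmp$tlab == "odd", ]
  expect_gt(nrow(odd), 10)
  expect_true(all(odd$dlab == "odd"))
  expect_true(mean(odd$tphase == odd$dphase) >= 0.95)
})
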