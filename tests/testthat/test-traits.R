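# Trait derivation: DOP screening, study-period windowing, movement rates,
# the daily activity index, and the trait-table join rules.

test_that("DOP screening is strict and preserves order", {
  f <- make_fixes("b1", hourly_times("2015-08-10 00:00:00", 3),
                  x = 1:3, y = 1:3, dop = c(5, 10, 10.1))
  out <- screen_fixes(f)
  expect_equal(out$dop, c(5, 10))          # dop = 10 retained, > 10 removed
  expect_equal(attr(out, "fraction_removed"), 1 / 3)

  expect_equal(nrow(screen_fixes(f[0, ])), 0)

  set.seed(1)
  big <- make_fixes("b1", hourly_times("2015-08-01 00:00:00", 1000),
                    x = 0, y = 0, dop = 2)
  big$dop[sample.int(1000, 30)] <- 11
  expect_equal(nrow(screen_fixes(big)), 970)

  f$dop[2] <- NA
  expect_error(screen_fixes(f), "dop")
})

test_that("study-period window is inclusive of 1 Aug and 30 Sep local time", {
  times <- as.POSIXct(c("2015-07-31 23:59:00", "2015-08-01 00:00:00",
                        "2015-09-30 23:59:00", "2015-10-01 00:01:00"),
                      tz = tz_study)
  f <- make_fixes("b1", times, x = 1:4, y = 1:4)
  out <- window_study_period(f)
  expect_equal(format(out$timestamp, "%m-%d"), c("08-01", "09-30"))
})

test_that("movement rates are Euclidean displacements over ~1 h gaps", {
  t0 <- hourly_times("2015-08-10 04:00:00", 2)
  f <- make_fixes("b1", t0, x = c(0, 300), y = c(0, 400))
  mv <- movement_rates(f)
  expect_equal(mv$rate, 500)               # 3-4-5 triangle
  expect_equal(mv$hour, 4)                 # stamped at the interval start

  f2 <- make_fixes("b1", t0, x = c(10, 10), y = c(-5, -5))
  expect_equal(movement_rates(f2)$rate, 0)

  # a screened-out middle fix leaves a 2 h gap: no rate emitted
  t3 <- hourly_times("2015-08-10 04:00:00", 3)[c(1, 3)]
  f3 <- make_fixes("b1", t3, x = c(0, 100), y = c(0, 0))
  expect_equal(nrow(movement_rates(f3)), 0)
})

test_that("movement rates equal the brute-force pairing on a gappy track", {
  set.seed(7)
  times <- hourly_times("2015-08-10 00:00:00", 48)
  keep <- sort(sample(48, 36))             # irregular gaps
  f <- rbind(
    make_fixes("b1", times[keep], x = cumsum(rnorm(36, 0, 200)),
               y = cumsum(rnorm(36, 0, 200))),
    make_fixes("b2", times[1:10], x = cumsum(rnorm(10, 0, 50)),
               y = cumsum(rnorm(10, 0, 50)))
  )
  got <- movement_rates(f)
  want <- brute_force_rates(f)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$rate, want$rate, tolerance = 1e-9)
  expect_equal(got$bear_id, want$bear_id)
})

test_that("activity index reproduces its analytic cases", {
  expect_equal(activity_index(100, 13, 0, 11), 1)    # only hunting hours
  expect_equal(activity_index(0, 13, 100, 11), -1)   # only nonhunting hours
  expect_equal(activity_index(130, 13, 110, 11), 0)  # equal rates
  expect_equal(activity_index(300, 10, 140, 14), 0.5, tolerance = 1e-12)
  expect_true(is.na(activity_index(0, 10, 0, 14)))   # undefined day
})

test_that("activity index stays within [-1, 1] over random inputs", {
  set.seed(99)
  for (i in 1:1000) {
    d_h <- runif(1, 1, 23)
    idx <- activity_index(rexp(1, 1 / 50), d_h, rexp(1, 1 / 50), 24 - d_h)
    expect_true(idx >= -1 && idx <= 1)
  }
})

test_that("daily index assigns 5-min windows by midpoint and drops zero days", {
  d <- "2015-08-21"
  hh <- hunting_hours(d)
  # one window wholly before hunting start, one straddling it with midpoint
  # inside, one in the middle of the hunting period
  starts <- c(hh$start - 600, hh$start - 100, hh$start + 3600)
  act <- data.frame(bear_id = "b1", timestamp = starts, value = c(6, 4, 10))
  out <- daily_activity_index(act)
  expect_equal(out$SA_h, 14)   # straddler's midpoint (+150 s) is inside
  expect_equal(out$SA_nh, 6)
  expect_equal(out$D_h + out$D_nh, 24)
  expect_true(out$index >= -1 && out$index <= 1)

  zero <- data.frame(bear_id = "b1",
                     timestamp = as.POSIXct(d, tz = tz_study) + c(3600, 50000),
                     value = c(0, 0))
  out0 <- daily_activity_index(zero)
  expect_equal(nrow(out0), 0)
  expect_equal(attr(out0, "dropped_days"), 1)
})

test_that("trait table applies the join, windowing and transform rules", {
  cfg <- synthetic_config(n_bears_per_sex = 4, years = 2015, seed = 5,
                          female_protection = TRUE, protection_frac = 1)
  ds <- simulate_dataset(cfg)
  tt <- build_trait_table(ds$relocations, ds$activity, ds$roads, ds$bear_years)

  # fully protected females contribute no rows anywhere
  expect_true(all(tt$movement$sex == "male"))
  expect_true(all(tt$distance$sex == "male"))

  # julian date 0 is 21 August
  aug21 <- tt$distance[tt$distance$date == as.Date("2015-08-21"), ]
  expect_true(all(aug21$julian_date == 0))

  # movement rows live in the 02:00-12:00 modeling window, all traits in season
  expect_true(all(tt$movement$hour >= 2 & tt$movement$hour <= 11))
  expect_true(all(format(tt$distance$date, "%m%d") >= "0801" &
                    format(tt$distance$date, "%m%d") <= "0930"))

  # afternoon fixes feed the distance trait even though movement ignores them
  fix_hours <- as.integer(format(ds$relocations$timestamp,
                                 tz = tz_study, format = "%H"))
  expect_true(any(fix_hours == 13))
  expect_true(all(tt$distance$n_fixes > 12))

  # zero rates are floored at 1 m/h before the log
  expect_true(all(tt$movement$log_rate >= 0))
  expect_true(all(tt$activity$index >= -1 & tt$activity$index <= 1))

  # pure function: identical rerun
  tt2 <- build_trait_table(ds$relocations, ds$activity, ds$roads, ds$bear_years)
  expect_identical(tt$movement, tt2$movement)
  expect_identical(tt$distance, tt2$distance)

  # telemetry without metadata is a data error
  orphan <- ds$relocations
  orphan$bear_id[which(orphan$dop <= 10)[1]] <- "ghost"
  expect_error(build_trait_table(orphan, ds$activity, ds$roads, ds$bear_years),
               "missing from metadata")
})
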