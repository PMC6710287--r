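# Synthetic generator: config validation, determinism, latent structure,
# track properties, and the harvest-fate process.

test_that("config validation enforces the documented invariants", {
  expect_error(synthetic_config(years = integer(0)), "years")
  expect_error(synthetic_config(n_bears_per_sex = 0), "n_bears_per_sex")
  expect_error(synthetic_config(road_spacing = -1), "road_spacing")
  expect_error(synthetic_config(sd_bear = -0.1), "SDs")
  expect_error(synthetic_config(ar1_phi = 1), "ar1_phi")
  expect_error(synthetic_config(base_harvest_prob = 0), "base_harvest_prob")
  expect_error(synthetic_config(dop_noise_frac = 1.5), "dop_noise_frac")
})

test_that("identical config and seed give identical datasets", {
  cfg <- synthetic_config(n_bears_per_sex = 3, years = 2015:2016, seed = 42)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$relocations, d2$relocations)
  expect_identical(d1$activity, d2$activity)
  expect_identical(d1$bear_years, d2$bear_years)
  expect_identical(d1$truth$bears, d2$truth$bears)
})

test_that("latent intercepts honor the configured variances", {
  # zero among-bear variance: all bears share the same latent intercepts
  p0 <- generate_population(synthetic_config(n_bears_per_sex = 5, sd_bear = 0,
                                             seed = 1))
  expect_true(all(p0$bears$b_move == 0) && all(p0$bears$b_dist == 0))

  # Monte-Carlo check of the among-bear SD at n = 2000
  p1 <- generate_population(synthetic_config(n_bears_per_sex = 1000,
                                             sd_bear = 1, seed = 2))
  expect_lt(abs(sd(p1$bears$b_move) - 1), 0.1)
  expect_lt(abs(sd(p1$bears$b_dist) - 1), 0.1)

  # implied repeatability is the variance ratio and lies in [0, 1]
  cfg <- synthetic_config()
  r <- implied_repeatability(cfg)
  expect_equal(r, cfg$sd_bear^2 /
                 (cfg$sd_bear^2 + cfg$sd_bearyear^2 + cfg$sd_resid^2))
  expect_true(r >= 0 && r <= 1)
})

test_that("ages increment by one between consecutive years of a bear", {
  p <- generate_population(synthetic_config(n_bears_per_sex = 10, seed = 3))
  for (b in unique(p$bear_years$bear_id)) {
    rows <- p$bear_years[p$bear_years$bear_id == b, ]
    rows <- rows[order(rows$year), ]
    if (nrow(rows) > 1) {
      expect_equal(diff(rows$age), diff(rows$year))
      expect_true(all(diff(rows$age) == 1))
    }
  }
})

test_that("null diel profile produces motionless, inactive bears", {
  cfg <- synthetic_config(n_bears_per_sex = 2, years = 2015, seed = 4,
                          diel_profile = function(hour) 0 * hour)
  ds <- simulate_dataset(cfg)
  mv <- movement_rates(ds$relocations)
  expect_true(all(mv$rate == 0))
  expect_true(all(ds$activity$value == 0))
})

test_that("the configured fraction of fixes gets DOP above 10", {
  cfg <- synthetic_config(n_bears_per_sex = 5, years = 2015,
                          dop_noise_frac = 0.03, seed = 6)
  ds <- simulate_dataset(cfg, activity = FALSE)
  n <- nrow(ds$relocations)
  frac <- mean(ds$relocations$dop > 10)
  expect_lt(abs(frac - 0.03), 3 * sqrt(0.03 * 0.97 / n) + 1e-9)
})

test_that("null selection yields the baseline harvest probability", {
  cfg <- synthetic_config(n_bears_per_sex = 400, years = 2015,
                          selection_dist = 0, selection_act = 0,
                          base_harvest_prob = 0.25, natural_death_prob = 0,
                          female_protection = FALSE, seed = 8)
  pop <- generate_population(cfg)
  by <- assign_fates(pop, latent_summaries(pop, cfg), cfg)
  rate <- mean(by$fate == "died")
  n <- nrow(by)
  expect_lt(abs(rate - 0.25), 3 * sqrt(0.25 * 0.75 / n))

  # and the fate is uncorrelated with the behavioral summaries
  s <- latent_summaries(pop, cfg)
  m <- merge(by, s, by = c("bear_id", "year"))
  ct <- cor.test(log(m$mean_dist), as.numeric(m$fate == "died"))
  expect_gt(ct$p.value, 0.001)
})

test_that("a baseline harvest probability near 1 kills every harvestable bear", {
  cfg <- synthetic_config(n_bears_per_sex = 30, years = 2015,
                          base_harvest_prob = 1 - 1e-9,
                          female_protection = FALSE, seed = 9)
  pop <- generate_population(cfg)
  by <- assign_fates(pop, latent_summaries(pop, cfg), cfg)
  expect_true(all(by$fate[by$harvestable] == "died"))
})

test_that("negative distance selection kills bears closer to roads", {
  # sign test over 50 fate simulations on fresh populations
  closer <- 0
  for (i in 1:50) {
    cfg <- synthetic_config(n_bears_per_sex = 40, years = 2015,
                            selection_dist = -1, selection_act = 0,
                            natural_death_prob = 0, seed = 100 + i)
    pop <- generate_population(cfg)
    s <- latent_summaries(pop, cfg)
    by <- assign_fates(pop, s, cfg)
    m <- merge(by[by$harvestable, ], s, by = c("bear_id", "year"))
    if (any(m$fate == "died") && any(m$fate == "survived") &&
        mean(m$mean_dist[m$fate == "died"]) <
        mean(m$mean_dist[m$fate == "survived"])) {
      closer <- closer + 1
    }
  }
  expect_gte(closer, 33)   # one-sided sign test, p < 0.02 under the null
})

test_that("fates, lifespans and truncation are internally consistent", {
  cfg <- synthetic_config(n_bears_per_sex = 15, years = 2013:2016, seed = 10)
  ds <- simulate_dataset(cfg, activity = FALSE)
  by <- ds$bear_years

  # remaining lifespan only for hunting deaths, zero iff died this season
  h <- by[!is.na(by$remaining_lifespan), ]
  expect_true(all(h$death_cause == "hunting"))
  expect_true(all(h$remaining_lifespan >= 0))
  expect_true(all((h$remaining_lifespan == 0) == (h$fate == "died")))

  # no bear-year after the death year; telemetry ends at the death date
  expect_true(all(is.na(by$death_year) | by$year <= by$death_year))
  dead <- by[by$fate == "died" & !is.na(by$death_date), ]
  for (i in seq_len(nrow(dead))) {
    fx <- ds$relocations[ds$relocations$bear_id == dead$bear_id[i], ]
    yr <- as.integer(format(fx$timestamp, "%Y"))
    fx <- fx[yr == dead$year[i], ]
    expect_true(all(as.Date(format(fx$timestamp, tz = tz_study,
                                   format = "%Y-%m-%d")) <= dead$death_date[i]))
  }

  # monitoring windows: telemetry only for monitored bear-years
  tele_by <- unique(paste(ds$relocations$bear_id,
                          format(ds$relocations$timestamp, "%Y")))
  expect_true(all(tele_by %in% paste(by$bear_id, by$year)))
})
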