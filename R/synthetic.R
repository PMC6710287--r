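# Synthetic telemetry generator. Emulates the data structure of a
# hunted, GPS-collared brown bear population: hourly relocations and 5-minute
# accelerometer summaries over the 1 Aug - 30 Sep window for each bear-year,
# a regular forest-road grid, two-level grouping (bear, bear-year) in every
# latent trait, AR1 residual autocorrelation, and season-level harvest fates
# whose log-odds depend on standardized behavioral summaries. Ground truth
# (latent intercepts, variance components, selection slopes) is returned for
# parameter-recovery testing.

#' Configuration for the synthetic telemetry generator
#'
#' Defaults describe the emulated study system: 40 bears per sex followed
#' over a 6-year monitoring window (a scaled-down version of the study
#' system's 14 years, long enough for harvest turnover to spread remaining
#' lifespans over several years), hourly GPS fixes and 5-minute activity
#' windows during
#' 1 Aug - 30 Sep, a 2-km road grid, lognormal step lengths with a
#' crepuscular diel profile and mild seasonal decline, among-bear /
#' among-year-within-bear / residual SDs of 0.35 / 0.25 / 0.90 on the log
#' scale (implied repeatability 0.123), AR1 residual correlation 0.4, a
#' per-season baseline harvest probability of 0.25 in a heavily harvested
#' population, and negative harvest selection on both distance to road and
#' the hunting-hours activity index.
#'
#' Bears enter the study in a staggered fashion (uniformly over the early
#' study years), carry a collar for `monitor_years` consecutive years (or
#' until death), and remain exposed to the harvest hazard for the rest of
#' the study: death years can therefore lie well beyond a bear's telemetry
#' window, as in collar-based field studies where fates come from harvest
#' registers.
#'
#' @param n_bears_per_sex Bears per sex (>= 1).
#' @param years Calendar years of the study (non-empty integer vector).
#' @param monitor_years Consecutive collar-years per bear (default 3).
#' @param fixes_per_hour GPS fixes per hour (default 1, hourly collars).
#' @param activity_interval Accelerometer summary window, minutes (default 5).
#' @param home_range_radius Attraction scale of the biased walk (m).
#' @param road_spacing Grid spacing of the synthetic road network (m).
#' @param arena_size Side of the square arena (m); derived from the
#'   population size when NULL.
#' @param diel_profile Function hour (0-23) -> relative movement intensity.
#' @param season_trend Function julian date (0 = 21 Aug) -> intensity
#'   multiplier.
#' @param rate_scale Baseline movement rate (m/h) multiplying the profiles.
#' @param sd_bear,sd_bearyear,sd_resid Among-bear, within-bear-among-year and
#'   residual SDs of each trait's latent log-scale value (>= 0).
#' @param ar1_phi Residual AR1 correlation, in (-1, 1).
#' @param mean_log_road_dist Mean log distance (log m) of home-range centers
#'   to the nearest road.
#' @param selection_dist,selection_act Log-odds slopes of seasonal harvest on
#'   the standardized bear-year mean distance to road and mean activity
#'   index (negative values: bears closer to roads / less day-active during
#'   hunting hours are harvested more).
#' @param base_harvest_prob Baseline per-season harvest probability, in (0,1).
#' @param natural_death_prob Per-season probability of non-hunting death.
#' @param female_protection If TRUE, females are non-harvestable (family
#'   group) in a `protection_frac` share of years.
#' @param protection_frac Fraction of female years protected.
#' @param dop_noise_frac Fraction of fixes given DOP > 10 (default 0.03).
#' @param seed Master seed; all child streams are derived from it by fixed
#'   offsets, so identical configs yield identical outputs.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_bears_per_sex = 40,
                             years = 2011:2016,
                             monitor_years = 3,
                             fixes_per_hour = 1,
                             activity_interval = 5,
                             home_range_radius = 600,
                             road_spacing = 2000,
                             arena_size = NULL,
                             diel_profile = default_diel_profile,
                             season_trend = default_season_trend,
                             rate_scale = 120,
                             sd_bear = 0.35,
                             sd_bearyear = 0.25,
                             sd_resid = 0.90,
                             ar1_phi = 0.4,
                             mean_log_road_dist = 6.3,
                             selection_dist = -0.8,
                             selection_act = -0.8,
                             base_harvest_prob = 0.25,
                             natural_death_prob = 0.02,
                             female_protection = TRUE,
                             protection_frac = 0.5,
                             dop_noise_frac = 0.03,
                             seed = 1) {
  if (length(years) == 0) stop("years must be a non-empty vector")
  if (n_bears_per_sex < 1) stop("n_bears_per_sex must be >= 1")
  if (road_spacing <= 0) stop("road_spacing must be positive")
  if (any(c(sd_bear, sd_bearyear, sd_resid) < 0)) stop("SDs must be >= 0")
  if (abs(ar1_phi) >= 1) stop("ar1_phi must lie in (-1, 1)")
  if (base_harvest_prob <= 0 || base_harvest_prob >= 1)
    stop("base_harvest_prob must lie in (0, 1)")
  if (dop_noise_frac < 0 || dop_noise_frac > 1)
    stop("dop_noise_frac must lie in [0, 1]")
  n_lines <- max(3, ceiling(sqrt(2 * n_bears_per_sex)) + 1)
  if (is.null(arena_size)) arena_size <- road_spacing * n_lines
  if (monitor_years < 1) stop("monitor_years must be >= 1")
  cfg <- list(n_bears_per_sex = n_bears_per_sex, years = sort(unique(years)),
              monitor_years = as.integer(monitor_years),
              fixes_per_hour = fixes_per_hour,
              activity_interval = activity_interval,
              home_range_radius = home_range_radius,
              road_spacing = road_spacing, arena_size = arena_size,
              diel_profile = diel_profile, season_trend = season_trend,
              rate_scale = rate_scale, sd_bear = sd_bear,
              sd_bearyear = sd_bearyear, sd_resid = sd_resid,
              ar1_phi = ar1_phi, mean_log_road_dist = mean_log_road_dist,
              selection_dist = selection_dist, selection_act = selection_act,
              base_harvest_prob = base_harvest_prob,
              natural_death_prob = natural_death_prob,
              female_protection = female_protection,
              protection_frac = protection_frac,
              dop_noise_frac = dop_noise_frac, seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Default crepuscular diel movement profile
#' @param hour Hour of day (0-23).
#' @return Relative intensity (dawn and dusk peaks, midday and night lows).
#' @export
default_diel_profile <- function(hour) {
  0.25 + 1.5 * exp(-((hour - 5.5)^2) / 6) + 1.5 * exp(-((hour - 20)^2) / 6)
}

#' Default seasonal intensity trend
#' @param jd Julian date with 0 = 21 August (season start).
#' @return Multiplier with a mild decline over the season.
#' @export
default_season_trend <- function(jd) exp(-0.004 * jd)

#' Implied repeatability of a generator configuration
#' @param config A `synthetic_config`.
#' @return sd_bear^2 / (sd_bear^2 + sd_bearyear^2 + sd_resid^2).
#' @export
implied_repeatability <- function(config) {
  v <- c(config$sd_bear, config$sd_bearyear, config$sd_resid)^2
  if (sum(v) == 0) return(0)
  v[1] / sum(v)
}

#' Generate the bear population with latent trait intercepts
#'
#' Each bear receives a sex, a staggered study-entry year, an age trajectory
#' (incrementing by one year between consecutive years), a home-range anchor
#' cell, and independent latent intercepts for the three traits drawn with
#' SD `sd_bear`; each bear-year from entry to study end adds a deviation
#' with SD `sd_bearyear`. The first `monitor_years` years from entry are
#' flagged as collar-monitored. Harvest fates are left unset.
#'
#' @param config A `synthetic_config`.
#' @return List with `bears`, `bear_years` (latents, ages, harvestability,
#'   `monitored` flag) and `truth` (generating parameters and implied
#'   repeatability).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  nb <- 2 * config$n_bears_per_sex
  ids <- sprintf("B%03d", seq_len(nb))
  sex <- rep(c("male", "female"), each = config$n_bears_per_sex)
  s <- config$road_spacing
  n_lines <- length(seq(s / 2, config$arena_size, by = s)[
    seq(s / 2, config$arena_size, by = s) < config$arena_size])
  slots <- expand.grid(col = seq_len(n_lines), row = seq_len(max(1, n_lines - 1)))
  if (nrow(slots) < nb) stop("arena too small for the population")
  slots <- slots[seq_len(nb), ]

  yrs <- config$years
  n_entry <- max(1L, length(yrs) - config$monitor_years + 1L)
  bears <- data.frame(
    bear_id = ids, sex = sex,
    cell_col = slots$col, cell_row = slots$row,
    side = rep(c(1, -1), length.out = nb),
    entry_year = yrs[sample.int(n_entry, nb, replace = TRUE)],
    age_entry = sample(3:12, nb, replace = TRUE),
    b_move = stats::rnorm(nb, 0, config$sd_bear),
    b_dist = stats::rnorm(nb, 0, config$sd_bear),
    b_act = stats::rnorm(nb, 0, config$sd_bear),
    stringsAsFactors = FALSE
  )

  by <- expand.grid(bear_id = ids, year = yrs, stringsAsFactors = FALSE)
  by <- by[order(by$bear_id, by$year), ]
  rownames(by) <- NULL
  bi <- match(by$bear_id, bears$bear_id)
  by <- by[by$year >= bears$entry_year[bi], , drop = FALSE]
  bi <- match(by$bear_id, bears$bear_id)
  rownames(by) <- NULL
  by$sex <- bears$sex[bi]
  by$age <- bears$age_entry[bi] + (by$year - bears$entry_year[bi])
  by$monitored <- by$year < bears$entry_year[bi] + config$monitor_years
  by$y_move <- stats::rnorm(nrow(by), 0, config$sd_bearyear)
  by$y_dist <- stats::rnorm(nrow(by), 0, config$sd_bearyear)
  by$y_act <- stats::rnorm(nrow(by), 0, config$sd_bearyear)
  by$harvestable <- TRUE
  if (config$female_protection) {
    fem <- by$sex == "female"
    by$harvestable[fem] <- stats::runif(sum(fem)) >= config$protection_frac
  }

  truth <- list(
    bears = bears[, c("bear_id", "sex", "b_move", "b_dist", "b_act")],
    bear_years = by[, c("bear_id", "year", "y_move", "y_dist", "y_act")],
    sd_bear = config$sd_bear, sd_bearyear = config$sd_bearyear,
    sd_resid = config$sd_resid, ar1_phi = config$ar1_phi,
    selection_dist = config$selection_dist,
    selection_act = config$selection_act,
    implied_repeatability = implied_repeatability(config)
  )
  list(bears = bears, bear_years = by, truth = truth)
}

# Marginal-SD AR1 series of length n.
ar1_series <- function(n, phi, sd_marginal) {
  if (sd_marginal == 0 || n == 0) return(numeric(n))
  innov <- stats::rnorm(n, 0, sd_marginal * sqrt(1 - phi^2))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd_marginal)
  if (n > 1) x[2:n] <- as.numeric(stats::filter(innov[2:n], phi, "recursive",
                                                init = x[1]))
  x
}

#' Simulate GPS tracks and accelerometer activity
#'
#' For every bear-year, hourly fixes over 1 Aug - 30 Sep are produced by a
#' biased random walk around a bear-year-specific center: log step length is
#' the sum of the diel and seasonal log-profiles, the bear and bear-year
#' latent intercepts, and an AR1 residual with marginal SD `sd_resid`; the
#' heading is drawn around the direction to the center with dispersion that
#' tightens as the bear strays beyond `home_range_radius`. Hourly
#' displacement therefore equals the latent step length, so log movement
#' rates extracted downstream carry exactly the configured variance
#' components. Activity values are the step intensity times lognormal noise,
#' modulated by a bear-specific day-activity preference so that the daily
#' activity index varies among individuals. A `dop_noise_frac` share of
#' fixes receives DOP > 10.
#'
#' @param population Output of [generate_population()].
#' @param roads A `road_network` (used only to anchor home-range centers).
#' @param config A `synthetic_config`.
#' @param activity If FALSE, skip accelerometer generation (faster for
#'   movement-only studies).
#' @return List with data frames `relocations` (bear_id, timestamp, x, y,
#'   dop) and `activity` (bear_id, timestamp, value), plus `centers`.
#' @export
simulate_tracks <- function(population, roads, config, activity = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  bears <- population$bears
  by <- population$bear_years
  if (nrow(by) == 0) stop("population is empty")
  s <- config$road_spacing
  tz <- study_centroid()$tz
  dt_sec <- 3600 / config$fixes_per_hour
  act_k <- as.integer(3600 / (config$activity_interval * 60))

  reloc <- vector("list", nrow(by))
  act <- if (activity) vector("list", nrow(by)) else NULL
  centers <- data.frame(bear_id = by$bear_id, year = by$year,
                        cx = NA_real_, cy = NA_real_, d_road = NA_real_)

  for (i in seq_len(nrow(by))) {
    b <- bears[match(by$bear_id[i], bears$bear_id), ]
    yr <- by$year[i]
    set.seed(config$seed + 101L * match(b$bear_id, bears$bear_id) +
               match(yr, config$years))

    t0 <- as.POSIXct(paste0(yr, "-08-01 00:00:00"), tz = tz)
    t1 <- as.POSIXct(paste0(yr, "-09-30 23:59:59"), tz = tz)
    times <- seq(t0, t1, by = dt_sec)
    n <- length(times)
    hrs <- as.numeric(format(times, "%H")) + as.numeric(format(times, "%M")) / 60
    jd <- julian_from_season_start(as.Date(format(times, "%Y-%m-%d")), yr)

    # bear-year center at latent distance from its anchor road line
    d_by <- exp(config$mean_log_road_dist + b$b_dist + by$y_dist[i])
    d_by <- min(max(d_by, 20), 0.45 * s)
    x_line <- s / 2 + (b$cell_col - 1) * s
    y_mid <- s / 2 + (b$cell_row - 0.5) * s
    cx <- x_line + b$side * d_by
    cy <- y_mid
    centers$cx[i] <- cx; centers$cy[i] <- cy; centers$d_road[i] <- d_by

    intensity <- config$diel_profile(hrs) * config$season_trend(jd)
    lat_move <- b$b_move + by$y_move[i]
    e <- ar1_series(n, config$ar1_phi, config$sd_resid)
    L <- ifelse(intensity > 0,
                config$rate_scale * intensity * exp(lat_move + e) / config$fixes_per_hour,
                0)

    x <- numeric(n); y <- numeric(n)
    x[1] <- cx; y[1] <- cy
    theta_noise <- stats::rnorm(n, 0, 1)
    u <- stats::runif(n)
    for (t in seq_len(n - 1)) {
      dxc <- cx - x[t]; dyc <- cy - y[t]
      dist_c <- sqrt(dxc^2 + dyc^2)
      if (dist_c < 1) {
        th <- 2 * pi * u[t]
      } else {
        sd_th <- pi * exp(-dist_c / config$home_range_radius)
        th <- atan2(dyc, dxc) + theta_noise[t] * sd_th
      }
      x[t + 1] <- x[t] + L[t] * cos(th)
      y[t + 1] <- y[t] + L[t] * sin(th)
    }

    dop <- stats::runif(n, 1, 8)
    nbad <- stats::rbinom(1, n, config$dop_noise_frac)
    if (nbad > 0) dop[sample.int(n, nbad)] <- stats::runif(nbad, 10.05, 25)
    reloc[[i]] <- data.frame(bear_id = b$bear_id, timestamp = times,
                             x = x, y = y, dop = dop)

    if (activity) {
      lat_act <- b$b_act + by$y_act[i]
      wins <- rep(times, each = act_k) +
        rep(seq(0, 3599, by = config$activity_interval * 60), times = n)
      hr_w <- rep(hrs, each = act_k)
      cday <- ifelse(hr_w >= 9 & hr_w < 17, 0.5, -0.5)
      base <- rep(L, each = act_k)
      val <- ifelse(base > 0,
                    0.1 * base * exp(lat_act * cday) *
                      stats::rlnorm(n * act_k, 0, 0.4),
                    0)
      act[[i]] <- data.frame(bear_id = b$bear_id, timestamp = wins, value = val)
    }
  }

  list(relocations = do.call(rbind, reloc),
       activity = if (activity) do.call(rbind, act) else NULL,
       centers = centers)
}

#' Latent per-bear-year behavioral summaries
#'
#' The generating values of the two behaviors the harvest hazard acts on:
#' the bear-year's home-range-center distance to the nearest road (m) and
#' its latent day-activity preference. Realized telemetry summaries
#' ([bear_year_summaries()]) are noisy measurements of these; the hazard is
#' driven by the latent values so that fates exist for bear-years outside
#' the collar-monitoring window.
#'
#' @param population Output of [generate_population()].
#' @param config A `synthetic_config`.
#' @return Data frame `bear_id`, `year`, `mean_dist`, `mean_act`.
#' @export
latent_summaries <- function(population, config) {
  by <- population$bear_years
  bi <- match(by$bear_id, population$bears$bear_id)
  d <- exp(config$mean_log_road_dist + population$bears$b_dist[bi] + by$y_dist)
  d <- pmin(pmax(d, 20), 0.45 * config$road_spacing)
  data.frame(bear_id = by$bear_id, year = by$year, mean_dist = d,
             mean_act = population$bears$b_act[bi] + by$y_act)
}

#' Per-bear-year behavioral summaries from telemetry
#'
#' Mean daily distance to the nearest road and mean daily activity index per
#' bear-year, from screened and windowed telemetry.
#'
#' @param relocations,activity Raw telemetry (activity may be NULL).
#' @param roads A `road_network`.
#' @param config A `synthetic_config`.
#' @return Data frame `bear_id`, `year`, `mean_dist`, `mean_act`.
#' @export
bear_year_summaries <- function(relocations, activity, roads, config) {
  tz <- study_centroid()$tz
  fixes <- window_study_period(screen_fixes(relocations), tz = tz)
  dd <- daily_road_distance(fixes, roads, tz)
  dd$year <- as.integer(format(dd$date, "%Y"))
  agg <- stats::aggregate(mean_dist ~ bear_id + year, dd, mean)
  if (!is.null(activity) && nrow(activity) > 0) {
    ai <- daily_activity_index(window_study_period(activity, tz = tz),
                               config$activity_interval)
    ai$year <- as.integer(format(ai$date, "%Y"))
    aa <- stats::aggregate(index ~ bear_id + year, ai, mean)
    agg <- merge(agg, aa, by = c("bear_id", "year"), all.x = TRUE)
    names(agg)[names(agg) == "index"] <- "mean_act"
    agg$mean_act[is.na(agg$mean_act)] <- 0
  } else {
    agg$mean_act <- 0
  }
  agg
}

#' Assign harvest fates from behavioral summaries
#'
#' Season-level logistic hazard: each harvestable bear-year is harvested with
#' probability `plogis(qlogis(base_harvest_prob) + selection_dist * z_dist +
#' selection_act * z_act)` where the z-scores standardize the bear-year mean
#' distance to road and mean activity index across harvestable bear-years.
#' Years are processed in order; a harvested bear contributes no later
#' bear-years. A small non-hunting mortality produces deaths with
#' `death_cause = "other"`. Remaining lifespan (death year minus observation
#' year) is defined only for hunting-killed bears.
#'
#' @param population Output of [generate_population()].
#' @param summaries Output of [bear_year_summaries()]; a missing summary for
#'   a harvestable bear-year is an error.
#' @param config A `synthetic_config`.
#' @return Data frame of bear-years up to each bear's death: `bear_id`,
#'   `year`, `sex`, `age`, `harvestable`, `fate`, `death_year`,
#'   `death_cause`, `death_date`, `remaining_lifespan`.
#' @export
assign_fates <- function(population, summaries, config) {
  by <- population$bear_years
  key <- paste(by$bear_id, by$year)
  skey <- paste(summaries$bear_id, summaries$year)
  miss <- key[by$harvestable & !key %in% skey]
  if (length(miss) > 0)
    stop("missing trait summaries for harvestable bear-years: ",
         paste(utils::head(miss), collapse = ", "))
  si <- match(key, skey)
  hv <- by$harvestable & !is.na(si)
  z_dist <- z_act <- rep(0, nrow(by))
  zd <- summaries$mean_dist[si[hv]]
  za <- summaries$mean_act[si[hv]]
  z_dist[hv] <- if (isTRUE(stats::sd(zd) > 0)) (zd - mean(zd)) / stats::sd(zd) else 0
  z_act[hv] <- if (isTRUE(stats::sd(za) > 0)) (za - mean(za)) / stats::sd(za) else 0

  set.seed(config$seed + 2L)
  death_year <- stats::setNames(rep(NA_integer_, nrow(population$bears)),
                                population$bears$bear_id)
  death_cause <- stats::setNames(rep(NA_character_, nrow(population$bears)),
                                 population$bears$bear_id)
  death_date <- stats::setNames(rep(as.Date(NA), nrow(population$bears)),
                                population$bears$bear_id)
  for (yr in config$years) {
    rows <- which(by$year == yr)
    rows <- rows[order(by$bear_id[rows])]
    for (r in rows) {
      id <- by$bear_id[r]
      if (!is.na(death_year[id])) next
      if (by$harvestable[r]) {
        p <- stats::plogis(stats::qlogis(config$base_harvest_prob) +
                             config$selection_dist * z_dist[r] +
                             config$selection_act * z_act[r])
        if (stats::runif(1) < p) {
          death_year[id] <- yr
          death_cause[id] <- "hunting"
          death_date[id] <- as.Date(paste0(yr, "-08-21")) +
            floor(stats::runif(1, 0, 41))
          next
        }
      }
      if (stats::runif(1) < config$natural_death_prob) {
        death_year[id] <- yr
        death_cause[id] <- "other"
        death_date[id] <- as.Date(paste0(yr, "-09-30"))
      }
    }
  }

  by$death_year <- as.integer(death_year[by$bear_id])
  by$death_cause <- death_cause[by$bear_id]
  by$death_date <- death_date[by$bear_id]
  keep <- is.na(by$death_year) | by$year <= by$death_year
  by <- by[keep, , drop = FALSE]
  by$fate <- ifelse(!is.na(by$death_year) & by$year == by$death_year &
                      by$death_cause == "hunting", "died", "survived")
  by$remaining_lifespan <- ifelse(!is.na(by$death_cause) &
                                    by$death_cause == "hunting",
                                  by$death_year - by$year, NA_real_)
  by$death_date[is.na(by$death_year) | by$year != by$death_year] <- NA
  rownames(by) <- NULL
  cols <- c("bear_id", "year", "sex", "age", "harvestable", "fate",
            "death_year", "death_cause", "death_date", "remaining_lifespan")
  if (!is.null(by$monitored)) cols <- c(cols, "monitored")
  by[, cols]
}

#' Simulate a complete synthetic dataset
#'
#' Orchestrates roads, population, harvest fates (driven by the latent
#' behavioral summaries, so they exist over the whole study horizon), and
#' GPS/accelerometer tracks for the collar-monitored bear-years of bears
#' still alive, truncated at each harvested bear's death date.
#'
#' @param config A `synthetic_config`.
#' @param activity Generate accelerometer data (default TRUE).
#' @return List `relocations`, `activity`, `roads`, `bear_years` (monitored
#'   bear-years only), `truth`, `config`.
#' @export
simulate_dataset <- function(config = synthetic_config(), activity = TRUE) {
  roads <- generate_roads(config$road_spacing, config$arena_size)
  pop <- generate_population(config)
  summ <- latent_summaries(pop, config)
  by_all <- assign_fates(pop, summ, config)
  by <- by_all[by_all$monitored, , drop = FALSE]
  rownames(by) <- NULL

  pop_mon <- pop
  keep <- paste(pop$bear_years$bear_id, pop$bear_years$year) %in%
    paste(by$bear_id, by$year)
  pop_mon$bear_years <- pop$bear_years[keep, , drop = FALSE]
  tracks <- simulate_tracks(pop_mon, roads, config, activity = activity)

  keep_telemetry <- function(df) {
    if (is.null(df)) return(NULL)
    yr <- as.integer(format(df$timestamp, "%Y"))
    k <- paste(df$bear_id, yr)
    ok <- k %in% paste(by$bear_id, by$year)
    df <- df[ok, , drop = FALSE]
    yr <- yr[ok]
    bi <- match(paste(df$bear_id, yr), paste(by$bear_id, by$year))
    dd <- by$death_date[bi]
    cut <- is.na(dd) | as.Date(format(df$timestamp,
                                      tz = study_centroid()$tz,
                                      format = "%Y-%m-%d")) <= dd
    df <- df[cut, , drop = FALSE]
    rownames(df) <- NULL
    df
  }

  pop$truth$harvest <- by_all[by_all$fate == "died", c("bear_id", "year")]
  list(relocations = keep_telemetry(tracks$relocations),
       activity = keep_telemetry(tracks$activity),
       roads = roads, bear_years = by, truth = pop$truth, config = config)
}
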