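# Trait derivation from raw telemetry: DOP screening, study-period
# windowing, hourly movement rates, the daily hunting-hours activity index,
# and daily distance to the nearest road with home-range road density.

#' Screen GPS fixes on dilution of precision
#'
#' Removes fixes whose DOP exceeds `dop_max` (strictly greater; a fix at the
#' threshold is retained). Order is preserved and the fraction removed is
#' attached as attribute `fraction_removed`.
#'
#' @param relocations Data frame with at least `bear_id`, `timestamp`, `x`,
#'   `y`, `dop`.
#' @param dop_max DOP threshold (default 10).
#' @return The screened data frame.
#' @export
screen_fixes <- function(relocations, dop_max = 10) {
  if (is.null(relocations$dop) || anyNA(relocations$dop))
    stop("every fix must carry a dop value")
  keep <- relocations$dop <= dop_max
  out <- relocations[keep, , drop = FALSE]
  attr(out, "fraction_removed") <-
    if (nrow(relocations)) 1 - sum(keep) / nrow(relocations) else 0
  out
}

local_date <- function(timestamp, tz = study_centroid()$tz) {
  as.Date(format(timestamp, tz = tz, format = "%Y-%m-%d"))
}

local_hour <- function(timestamp, tz = study_centroid()$tz) {
  as.integer(format(timestamp, tz = tz, format = "%H"))
}

#' Restrict rows to the 1 August - 30 September study window
#'
#' Keeps rows whose local calendar date falls between 1 August and
#' 30 September (inclusive), optionally of one given year. Works on any data
#' frame with a `timestamp` (POSIXct) or `date` (Date) column.
#'
#' @param rows Data frame.
#' @param year Optional calendar year filter.
#' @param tz Timezone used to map instants to local dates.
#' @return The windowed data frame.
#' @export
window_study_period <- function(rows, year = NULL, tz = study_centroid()$tz) {
  d <- if (!is.null(rows$date)) as.Date(rows$date) else local_date(rows$timestamp, tz)
  md <- format(d, "%m%d")
  keep <- md >= "0801" & md <= "0930"
  if (!is.null(year)) keep <- keep & format(d, "%Y") == as.character(year)
  rows[keep, , drop = FALSE]
}

#' Hourly movement rates from consecutive fixes
#'
#' Computes the Euclidean displacement between consecutive fixes of the same
#' bear whose time gap is one hour within `tol_min` minutes; other gaps
#' (e.g. spanning a screened fix) yield no rate. The rate (m/h) is stamped at
#' the interval start.
#'
#' @param relocations Screened, windowed fixes.
#' @param tol_min Gap tolerance around 60 minutes (default 5).
#' @param tz Timezone for local hour-of-day stamps.
#' @return Data frame `bear_id`, `timestamp`, `hour`, `rate`.
#' @export
movement_rates <- function(relocations, tol_min = 5, tz = study_centroid()$tz) {
  empty <- data.frame(bear_id = character(), timestamp = as.POSIXct(character()),
                      hour = integer(), rate = numeric())
  if (nrow(relocations) == 0) return(empty)
  ord <- order(relocations$bear_id, relocations$timestamp)
  r <- relocations[ord, ]
  n <- nrow(r)
  if (n < 2) return(empty)
  same <- r$bear_id[-n] == r$bear_id[-1]
  dt_min <- as.numeric(difftime(r$timestamp[-1], r$timestamp[-n], units = "mins"))
  ok <- same & abs(dt_min - 60) <= tol_min
  i <- which(ok)
  out <- data.frame(
    bear_id = r$bear_id[i],
    timestamp = r$timestamp[i],
    hour = local_hour(r$timestamp[i], tz),
    rate = sqrt((r$x[i + 1] - r$x[i])^2 + (r$y[i + 1] - r$y[i])^2)
  )
  rownames(out) <- NULL
  out
}

#' Daily hunting-hours activity index
#'
#' The duty-cycle corrected contrast of activity rates inside versus outside
#' legal hunting hours:
#' \deqn{(SA_h/D_h - SA_nh/D_nh) / (SA_h/D_h + SA_nh/D_nh)}
#' where `SA_h`/`SA_nh` are summed activity values during hunting and
#' nonhunting hours and `D_h`/`D_nh` the respective durations. The index is
#' -1 for a bear only active outside hunting hours and 1 for a bear only
#' active within them.
#'
#' @param sa_h,sa_nh Summed activity inside/outside hunting hours (>= 0).
#' @param d_h,d_nh Durations (hours) of the two periods; must sum to 24.
#' @return Index in [-1, 1], or NA when the bear recorded no activity at all
#'   that day (undefined ratio).
#' @export
activity_index <- function(sa_h, d_h, sa_nh, d_nh) {
  stopifnot(all(sa_h >= 0), all(sa_nh >= 0), all(d_h > 0), all(d_nh > 0))
  rh <- sa_h / d_h
  rn <- sa_nh / d_nh
  ifelse(rh + rn == 0, NA_real_, (rh - rn) / (rh + rn))
}

#' Daily activity index per bear-day
#'
#' Assigns each accelerometer window to the hunting or nonhunting period by
#' its midpoint, sums activity within each period per bear and local date,
#' and evaluates [activity_index()]. Days on which a bear recorded zero total
#' activity are dropped (undefined index) and counted in attribute
#' `dropped_days`.
#'
#' @param activity Data frame `bear_id`, `timestamp` (window start), `value`.
#' @param interval_min Window length in minutes (default 5).
#' @param lat,lon,tz Location/timezone for the hunting-hours computation.
#' @return Data frame `bear_id`, `date`, `SA_h`, `SA_nh`, `D_h`, `D_nh`,
#'   `index`.
#' @export
daily_activity_index <- function(activity, interval_min = 5,
                                 lat = study_centroid()$lat,
                                 lon = study_centroid()$lon,
                                 tz = study_centroid()$tz) {
  if (nrow(activity) == 0)
    return(data.frame(bear_id = character(), date = as.Date(character()),
                      SA_h = numeric(), SA_nh = numeric(),
                      D_h = numeric(), D_nh = numeric(), index = numeric()))
  mid <- activity$timestamp + interval_min * 30   # midpoint, seconds
  date <- local_date(mid, tz)
  udates <- sort(unique(date))
  hh <- lapply(udates, hunting_hours, lat = lat, lon = lon, tz = tz)
  names(hh) <- as.character(udates)
  di <- match(as.character(date), names(hh))
  start <- vapply(hh, function(h) as.numeric(h$start), 0)[di]
  end <- vapply(hh, function(h) as.numeric(h$end), 0)[di]
  in_h <- as.numeric(mid) >= start & as.numeric(mid) < end

  key <- interaction(activity$bear_id, date, drop = TRUE)
  sa_h <- rowsum(activity$value * in_h, key)
  sa_nh <- rowsum(activity$value * !in_h, key)
  first <- !duplicated(key)
  kf <- key[first]
  o <- match(levels(key), kf)
  out <- data.frame(
    bear_id = activity$bear_id[first][o],
    date = date[first][o],
    SA_h = as.numeric(sa_h[levels(key), 1]),
    SA_nh = as.numeric(sa_nh[levels(key), 1])
  )
  dh <- vapply(hh, function(h) h$D_h, 0)[match(as.character(out$date), names(hh))]
  out$D_h <- dh
  out$D_nh <- 24 - dh
  out$index <- activity_index(out$SA_h, out$D_h, out$SA_nh, out$D_nh)
  dropped <- sum(is.na(out$index))
  out <- out[!is.na(out$index), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_days") <- dropped
  out
}

#' Daily mean distance to the nearest road
#'
#' Per-fix minimum Euclidean distance to the road network, averaged per bear
#' and local date.
#'
#' @param relocations Screened, windowed fixes.
#' @param roads A `road_network`.
#' @param tz Timezone for local dates.
#' @return Data frame `bear_id`, `date`, `mean_dist` (m), `n_fixes`.
#' @export
daily_road_distance <- function(relocations, roads, tz = study_centroid()$tz) {
  d <- distance_to_road(relocations$x, relocations$y, roads)
  date <- local_date(relocations$timestamp, tz)
  key <- interaction(relocations$bear_id, date, drop = TRUE)
  first <- !duplicated(key)
  o <- match(levels(key), key[first])
  out <- data.frame(
    bear_id = relocations$bear_id[first][o],
    date = date[first][o],
    mean_dist = as.numeric(rowsum(d, key)[levels(key), 1] /
                             rowsum(rep(1, length(d)), key)[levels(key), 1]),
    n_fixes = as.integer(rowsum(rep(1L, length(d)), key)[levels(key), 1])
  )
  rownames(out) <- NULL
  out
}

julian_from_season_start <- function(date, year) {
  if (length(date) == 0) return(numeric(0))
  as.numeric(as.Date(date) - as.Date(paste0(year, "-08-21")))
}

#' Build the modeling trait table
#'
#' Runs the full derivation chain - DOP screening, study-period windowing,
#' movement rates (restricted to the 02:00-12:00 window used for modeling),
#' daily activity index, daily mean distance to road with home-range road
#' density - and joins each trait to bear-year metadata. Only bear-years in
#' which the bear was legally harvestable (not in a family group) contribute
#' rows. Movement and distance responses are log-transformed; rates below
#' `min_rate` m/h are floored at `min_rate` so resting bouts survive the log.
#'
#' @param relocations,activity Raw telemetry (see [simulate_dataset()] or the
#'   CSV readers for the schema).
#' @param roads A `road_network`.
#' @param bear_years Metadata with `bear_id`, `year`, `sex`, `age`,
#'   `harvestable`, `fate` ("died"/"survived"), `death_year`, `death_cause`,
#'   `remaining_lifespan`.
#' @param dop_max DOP screening threshold.
#' @param move_hours Inclusive local start-hour range of movement intervals
#'   kept for modeling; default `c(2, 11)` keeps intervals within
#'   02:00-12:00.
#' @param min_rate Floor (m/h) applied before the log transform.
#' @param interval_min Accelerometer window length (minutes).
#' @param lat,lon,tz Study location and timezone.
#' @return Object of class `trait_table`: list with data frames `movement`,
#'   `activity`, `distance`, plus `screening` diagnostics.
#' @export
build_trait_table <- function(relocations, activity, roads, bear_years,
                              dop_max = 10, move_hours = c(2, 11),
                              min_rate = 1, interval_min = 5,
                              lat = study_centroid()$lat,
                              lon = study_centroid()$lon,
                              tz = study_centroid()$tz) {
  stopifnot(all(c("bear_id", "year", "sex", "age", "harvestable", "fate")
                %in% names(bear_years)))
  fixes <- screen_fixes(relocations, dop_max)
  frac_removed <- attr(fixes, "fraction_removed")
  fixes <- window_study_period(fixes, tz = tz)
  fixes$year <- as.integer(format(local_date(fixes$timestamp, tz), "%Y"))

  by <- bear_years
  by$bear_year <- paste(by$bear_id, by$year, sep = "_")
  harv <- by[by$harvestable, , drop = FALSE]
  meta_cols <- c("bear_year", "sex", "age", "fate", "remaining_lifespan")
  if (is.null(harv$remaining_lifespan)) harv$remaining_lifespan <- NA_real_
  if (is.null(harv$death_cause)) harv$death_cause <- NA_character_
  meta <- harv[, c(meta_cols, "death_cause")]

  join_meta <- function(df) {
    df$bear_year <- paste(df$bear_id, df$year, sep = "_")
    df <- df[df$bear_year %in% harv$bear_year, , drop = FALSE]
    m <- merge(df, meta, by = "bear_year", sort = FALSE)
    m$fate <- factor(m$fate, levels = c("survived", "died"))
    m
  }

  # telemetry without any metadata row at all is a data error
  obs_by <- unique(paste(fixes$bear_id, fixes$year, sep = "_"))
  if (any(!obs_by %in% by$bear_year))
    stop("telemetry present for bear-years missing from metadata: ",
         paste(utils::head(setdiff(obs_by, by$bear_year)), collapse = ", "))

  ## movement
  mv <- movement_rates(fixes, tz = tz)
  mv$year <- as.integer(format(local_date(mv$timestamp, tz), "%Y"))
  mv <- mv[mv$hour >= move_hours[1] & mv$hour <= move_hours[2], , drop = FALSE]
  mv$julian_date <- julian_from_season_start(local_date(mv$timestamp, tz), mv$year)
  mv$log_rate <- log(pmax(mv$rate, min_rate))
  movement <- join_meta(mv)

  ## activity
  act <- window_study_period(activity, tz = tz)
  ai <- daily_activity_index(act, interval_min, lat, lon, tz)
  dropped_days <- attr(ai, "dropped_days")
  ai$year <- as.integer(format(ai$date, "%Y"))
  ai$julian_date <- julian_from_season_start(ai$date, ai$year)
  activity_tab <- join_meta(ai)

  ## distance + road density
  dd <- daily_road_distance(fixes, roads, tz)
  dd$year <- as.integer(format(dd$date, "%Y"))
  dd$julian_date <- julian_from_season_start(dd$date, dd$year)
  dd$log_dist <- log(pmax(dd$mean_dist, 1))
  distance <- join_meta(dd)
  if (nrow(distance)) {
    dens <- vapply(split(seq_len(nrow(fixes)),
                         paste(fixes$bear_id, fixes$year, sep = "_")),
                   function(ix) {
                     if (length(ix) < 3) return(NA_real_)
                     tryCatch(home_range_road_density(fixes$x[ix], fixes$y[ix],
                                                      roads)$density,
                              error = function(e) NA_real_)
                   }, 0)
    distance$road_density <- dens[distance$bear_year]
    excluded <- unique(distance$bear_year[is.na(distance$road_density)])
    distance <- distance[!is.na(distance$road_density), , drop = FALSE]
  } else {
    distance$road_density <- numeric(0)
    excluded <- character(0)
  }

  structure(list(movement = movement, activity = activity_tab,
                 distance = distance,
                 screening = list(dop_fraction_removed = frac_removed,
                                  activity_days_dropped = dropped_days,
                                  bear_years_without_mcp = excluded)),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat("Trait table\n")
  for (tr in c("movement", "activity", "distance")) {
    d <- x[[tr]]
    cat(sprintf("  %-9s %6d rows, %3d bears, %3d bear-years\n", tr, nrow(d),
                length(unique(d$bear_id)), length(unique(d$bear_year))))
  }
  cat(sprintf("  DOP screening removed %.2f%% of fixes\n",
              100 * x$screening$dop_fraction_removed))
  invisible(x)
}
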