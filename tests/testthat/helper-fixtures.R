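# Fixture builders and independent oracles shared across test files.

tz_study <- study_centroid()$tz

make_fixes <- function(bear_id, times, x, y, dop = 2) {
  data.frame(bear_id = bear_id, timestamp = times, x = x, y = y, dop = dop)
}

hourly_times <- function(start, n, tz = tz_study) {
  as.POSIXct(start, tz = tz) + 3600 * (seq_len(n) - 1)
}

empty_activity <- function() {
  data.frame(bear_id = character(), timestamp = as.POSIXct(character()),
             value = numeric())
}

# O(n^2) oracle for movement rates: examine every ordered pair of fixes of
# the same bear and emit the displacement for pairs ~1 h apart with no fix
# in between.
brute_force_rates <- function(fixes, tol_min = 5) {
  out <- data.frame(bear_id = character(), timestamp = as.POSIXct(character()),
                    rate = numeric())
  for (b in unique(fixes$bear_id)) {
    f <- fixes[fixes$bear_id == b, ]
    f <- f[order(f$timestamp), ]
    n <- nrow(f)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j <= i) next
        dt <- as.numeric(difftime(f$timestamp[j], f$timestamp[i], units = "mins"))
        between <- sum(f$timestamp > f$timestamp[i] & f$timestamp < f$timestamp[j])
        if (between == 0 && abs(dt - 60) <= tol_min) {
          out <- rbind(out, data.frame(
            bear_id = b, timestamp = f$timestamp[i],
            rate = sqrt((f$x[j] - f$x[i])^2 + (f$y[j] - f$y[i])^2)))
        }
      }
    }
  }
  out[order(out$bear_id, out$timestamp), ]
}

# O(n^3) convex hull area oracle: an ordered pair (i, j) is a hull edge iff
# every other point lies on its left; the area follows from summing the
# cross products of the detected edges around the centroid.
brute_force_hull_area <- function(x, y) {
  n <- length(x)
  stopifnot(n <= 20)
  edges <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ok <- TRUE
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        cr <- (x[j] - x[i]) * (y[k] - y[i]) - (y[j] - y[i]) * (x[k] - x[i])
        if (cr < -1e-9) { ok <- FALSE; break }
      }
      if (ok) edges[[length(edges) + 1]] <- c(i, j)
    }
  }
  # walk the edges into a cycle starting from any vertex
  e <- do.call(rbind, edges)
  start <- e[1, 1]
  ord <- c(start)
  cur <- start
  repeat {
    nxt <- e[e[, 1] == cur, 2][1]
    if (nxt == start) break
    ord <- c(ord, nxt)
    cur <- nxt
    if (length(ord) > n) stop("oracle failed to close the hull")
  }
  hx <- x[ord]; hy <- y[ord]
  xn <- c(hx[-1], hx[1]); yn <- c(hy[-1], hy[1])
  abs(sum(hx * yn - xn * hy)) / 2
}

# Direct simulation from the nested mixed model (no telemetry layer): used
# for coefficient / phi recovery tests of the fitting engine itself.
simulate_lifespan_lmm <- function(seed, n_bears = 30, n_years = 2,
                                  n_days = 20, beta_rl = 0.05,
                                  sd_bear = 0.3, sd_by = 0.2,
                                  sd_resid = 0.4, phi = 0.3) {
  set.seed(seed)
  nby <- n_bears * n_years
  bear <- rep(sprintf("B%02d", seq_len(n_bears)), each = n_years)
  rl <- pmax(0, rep(sample(0:8, n_bears, TRUE), each = n_years) -
               rep(seq_len(n_years) - 1, n_bears))
  bb <- rep(rnorm(n_bears, 0, sd_bear), each = n_years * n_days)
  yy <- rep(rnorm(nby, 0, sd_by), each = n_days)
  e <- as.vector(vapply(seq_len(nby), function(i)
    harvestsel:::ar1_series(n_days, phi, sd_resid), numeric(n_days)))
  data.frame(
    log_dist = 6 + beta_rl * rep(rl, each = n_days) + bb + yy + e,
    remaining_lifespan = rep(rl, each = n_days),
    age = rep(sample(3:12, n_bears, TRUE), each = n_years * n_days),
    julian_date = rep(seq_len(n_days), nby),
    road_density = rep(runif(nby, 0.5, 1.5), each = n_days),
    bear_id = rep(bear, each = n_days),
    bear_year = rep(paste(bear, rep(seq_len(n_years), n_bears), sep = "_"),
                    each = n_days),
    date = as.Date("2015-08-01") + rep(seq_len(n_days), nby)
  )
}

# Direct simulation from the by-fate hour-smooth movement model.
simulate_fate_interaction <- function(seed, n_bears = 40, n_years = 3) {
  set.seed(seed)
  nby <- n_bears * n_years
  bear <- rep(sprintf("B%02d", seq_len(n_bears)), each = n_years)
  by <- paste(bear, rep(seq_len(n_years), n_bears), sep = "_")
  fate <- sample(c("survived", "died"), nby, TRUE, prob = c(0.65, 0.35))
  age <- rep(sample(3:12, n_bears, TRUE), each = n_years) +
    rep(seq_len(n_years), n_bears) - 1
  days <- 61; hours <- 2:11
  n_per <- days * length(hours)
  hour <- rep(rep(hours, days), nby)
  jdate <- rep(rep(seq(-20, 40), each = length(hours)), nby)
  bb <- rep(rnorm(n_bears, 0, 0.35), each = n_years * n_per)
  yy <- rep(rnorm(nby, 0, 0.25), each = n_per)
  fate_l <- rep(fate, each = n_per)
  f_s <- 0.3 * exp(-((hour - 4)^2) / 4) + 0.02 * hour
  f_d <- 1.0 * exp(-((hour - 4)^2) / 4) - 0.03 * hour
  g <- 0.2 * sin((jdate + 20) / 61 * pi) - 0.004 * jdate
  e <- as.vector(replicate(nby, harvestsel:::ar1_series(n_per, 0.4, 0.9)))
  data.frame(log_rate = 4.5 + ifelse(fate_l == "survived", f_s, f_d) + g +
               bb + yy + e,
             hour = hour, julian_date = jdate, age = rep(age, each = n_per),
             fate = fate_l, bear_id = rep(bear, each = n_per),
             bear_year = rep(by, each = n_per),
             timestamp = as.POSIXct("2015-08-01", tz = "UTC") +
               seq_len(nby * n_per))
}
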