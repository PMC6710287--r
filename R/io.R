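# Plain-text interchange: Movebank-like CSV for telemetry, GeoJSON
# LineStrings for roads, JSON for ground truth, CSV for trait tables.
# Timestamps are written as ISO-8601 UTC and mapped back to the study
# timezone on read.

ts_out <- function(x) format(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")

ts_in <- function(x, tz = study_centroid()$tz) {
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OSZ")
  fallback <- is.na(out)
  if (any(fallback)) out[fallback] <- as.POSIXct(x[fallback], tz = tz)
  attr(out, "tzone") <- tz
  out
}

#' Write / read relocation CSV
#'
#' Columns: `bear_id`, `timestamp` (ISO-8601 UTC), `x`, `y` (projected
#' meters), `dop`.
#'
#' @param relocations Data frame of fixes.
#' @param path CSV path.
#' @export
write_relocations <- function(relocations, path) {
  out <- relocations
  out$timestamp <- ts_out(out$timestamp)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_relocations
#' @export
read_relocations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bear_id", "timestamp", "x", "y", "dop")
  if (!all(need %in% names(d)))
    stop("relocation CSV must have columns: ", paste(need, collapse = ", "))
  d$timestamp <- ts_in(d$timestamp)
  d
}

#' Write / read activity CSV
#'
#' Columns: `bear_id`, `timestamp` (window start, ISO-8601 UTC), `value`.
#'
#' @param activity Data frame of accelerometer windows.
#' @param path CSV path.
#' @export
write_activity <- function(activity, path) {
  out <- activity
  out$timestamp <- ts_out(out$timestamp)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_activity
#' @export
read_activity <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bear_id", "timestamp", "value")
  if (!all(need %in% names(d)))
    stop("activity CSV must have columns: ", paste(need, collapse = ", "))
  d$timestamp <- ts_in(d$timestamp)
  d
}

#' Write / read bear-year metadata CSV
#'
#' Columns: `bear_id`, `year`, `sex`, `age`, `harvestable`, `fate`
#' ("died"/"survived"), `death_year`, `death_cause`, `remaining_lifespan`.
#'
#' @param bear_years Metadata data frame.
#' @param path CSV path.
#' @export
write_bear_years <- function(bear_years, path) {
  out <- bear_years
  if (!is.null(out$death_date)) out$death_date <- as.character(out$death_date)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bear_years
#' @export
read_bear_years <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bear_id", "year", "sex", "age", "harvestable", "fate")
  if (!all(need %in% names(d)))
    stop("bear-year CSV must have columns: ", paste(need, collapse = ", "))
  if (!is.null(d$death_date)) d$death_date <- as.Date(d$death_date)
  if (is.null(d$remaining_lifespan)) d$remaining_lifespan <- NA_real_
  if (is.null(d$death_cause)) d$death_cause <- NA_character_
  d$harvestable <- as.logical(d$harvestable)
  d
}

#' Write / read a road network as GeoJSON LineStrings
#'
#' Coordinates are projected meters (the same system as the relocations),
#' stored as a FeatureCollection of LineString features.
#'
#' @param roads A `road_network`.
#' @param path GeoJSON path.
#' @export
write_roads_geojson <- function(roads, path) {
  stopifnot(inherits(roads, "road_network"))
  features <- lapply(roads$polylines, function(p) {
    list(type = "Feature", properties = stats::setNames(list(), character(0)),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(p)),
                                              function(i) c(p[i, 1], p[i, 2]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roads_geojson
#' @export
read_roads_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  if (is.null(g$features)) stop("not a GeoJSON FeatureCollection")
  polylines <- lapply(g$features, function(f) {
    cc <- f$geometry$coordinates
    do.call(rbind, lapply(cc, function(p) c(as.numeric(p[[1]]),
                                            as.numeric(p[[2]]))))
  })
  road_network(polylines)
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits relocations.csv, activity.csv, roads.geojson, bear_years.csv and
#' truth.json.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_relocations(dataset$relocations, file.path(dir, "relocations.csv"))
  if (!is.null(dataset$activity))
    write_activity(dataset$activity, file.path(dir, "activity.csv"))
  write_roads_geojson(dataset$roads, file.path(dir, "roads.geojson"))
  write_bear_years(dataset$bear_years, file.path(dir, "bear_years.csv"))
  truth <- dataset$truth
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Write / read a trait table as three CSVs
#'
#' movement.csv, activity.csv and distance.csv in `dir`, with the column
#' layout produced by [build_trait_table()].
#'
#' @param tt A `trait_table`.
#' @param dir Directory.
#' @export
write_trait_table <- function(tt, dir) {
  stopifnot(inherits(tt, "trait_table"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tr in c("movement", "activity", "distance")) {
    out <- tt[[tr]]
    if (!is.null(out$timestamp)) out$timestamp <- ts_out(out$timestamp)
    if (!is.null(out$date)) out$date <- as.character(out$date)
    utils::write.csv(out, file.path(dir, paste0(tr, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(dir) {
  tt <- list()
  for (tr in c("movement", "activity", "distance")) {
    f <- file.path(dir, paste0(tr, ".csv"))
    if (!file.exists(f)) stop("missing trait CSV: ", f)
    d <- utils::read.csv(f, stringsAsFactors = FALSE)
    if (!is.null(d$timestamp)) d$timestamp <- ts_in(d$timestamp)
    if (!is.null(d$date)) d$date <- as.Date(d$date)
    if (!is.null(d$fate)) d$fate <- factor(d$fate, levels = c("survived", "died"))
    tt[[tr]] <- d
  }
  tt$screening <- list(dop_fraction_removed = NA_real_,
                       activity_days_dropped = NA_integer_,
                       bear_years_without_mcp = character(0))
  structure(tt, class = "trait_table")
}
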