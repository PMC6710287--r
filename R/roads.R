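# Road-network geometry: a synthetic grid generator, point-to-polyline
# distance, minimum convex polygon home ranges and road density within them.
# All coordinates are meters in a shared projected system.

#' Construct a road network from polylines
#'
#' @param polylines List of numeric matrices, each n x 2 (x, y in meters)
#'   describing one polyline with at least two vertices.
#' @return An object of class `road_network`.
#' @export
road_network <- function(polylines) {
  stopifnot(is.list(polylines), length(polylines) > 0)
  for (p in polylines) {
    if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 2)
      stop("each polyline must be an n x 2 matrix with n >= 2")
    seg_len <- sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
    if (any(seg_len <= 0)) stop("every road segment must have positive length")
  }
  structure(list(polylines = polylines), class = "road_network")
}

# Flatten a network into a segment table (x1, y1, x2, y2).
road_segments <- function(roads) {
  segs <- lapply(roads$polylines, function(p) {
    n <- nrow(p)
    cbind(p[-n, 1], p[-n, 2], p[-1, 1], p[-1, 2])
  })
  do.call(rbind, segs)
}

#' Total length of a road network (meters)
#' @param roads A `road_network`.
#' @export
road_length <- function(roads) {
  s <- road_segments(roads)
  sum(sqrt((s[, 3] - s[, 1])^2 + (s[, 4] - s[, 2])^2))
}

#' Generate a rectangular grid of roads
#'
#' Produces an offset grid: lines at `spacing/2 + k * spacing` in both
#' directions across a square arena, emulating a dense, regular forest-road
#' network whose density is controlled by a single spacing parameter. The
#' layout is fully deterministic.
#'
#' @param spacing Distance between parallel roads (m), > 0.
#' @param arena_size Side of the square arena (m); must be >= spacing.
#' @return A `road_network` whose polylines span the arena.
#' @export
generate_roads <- function(spacing, arena_size) {
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0)
    stop("road spacing must be a single positive number")
  if (arena_size < spacing)
    stop("arena_size must be at least the road spacing")
  pos <- seq(spacing / 2, arena_size, by = spacing)
  pos <- pos[pos < arena_size]
  vert <- lapply(pos, function(x) cbind(c(x, x), c(0, arena_size)))
  horiz <- lapply(pos, function(y) cbind(c(0, arena_size), c(y, y)))
  road_network(c(vert, horiz))
}

#' Distance from points to the nearest road
#'
#' Minimum Euclidean distance from each point to any segment of the network.
#'
#' @param x,y Numeric vectors of projected coordinates (m).
#' @param roads A `road_network`.
#' @return Numeric vector of distances (m).
#' @export
distance_to_road <- function(x, y, roads) {
  if (!inherits(roads, "road_network") || length(roads$polylines) == 0)
    stop("a non-empty road_network is required")
  stopifnot(length(x) == length(y))
  segs <- road_segments(roads)
  d <- rep(Inf, length(x))
  for (i in seq_len(nrow(segs))) {
    x1 <- segs[i, 1]; y1 <- segs[i, 2]; x2 <- segs[i, 3]; y2 <- segs[i, 4]
    dx <- x2 - x1; dy <- y2 - y1
    tt <- ((x - x1) * dx + (y - y1) * dy) / (dx * dx + dy * dy)
    tt <- pmin(pmax(tt, 0), 1)
    d <- pmin(d, sqrt((x - (x1 + tt * dx))^2 + (y - (y1 + tt * dy))^2))
  }
  d
}

#' Minimum convex polygon (100% MCP)
#'
#' Convex hull of a set of relocations, the home-range proxy used for the
#' road-density covariate.
#'
#' @param x,y Relocation coordinates (m).
#' @return Matrix of hull vertices (counter-clockwise, not closed), or an
#'   error if fewer than 3 non-collinear points are supplied.
#' @export
mcp_polygon <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("at least 3 relocations are required for an MCP")
  idx <- grDevices::chull(x, y)     # clockwise order
  hull <- cbind(x[idx], y[idx])[rev(seq_along(idx)), , drop = FALSE]
  if (nrow(hull) < 3 || abs(polygon_area(hull)) < 1e-9)
    stop("relocations are collinear; MCP undefined")
  hull
}

#' Polygon area by the shoelace formula (m^2)
#' @param poly Matrix of vertices (counter-clockwise, not closed).
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Clip one segment to a convex polygon (Cyrus-Beck). Returns clipped length.
clip_segment_length <- function(p1, p2, poly) {
  n <- nrow(poly)
  d <- p2 - p1
  t0 <- 0; t1 <- 1
  for (i in seq_len(n)) {
    a <- poly[i, ]
    b <- poly[if (i == n) 1 else i + 1, ]
    e <- b - a                      # edge direction, CCW: inside is left
    nrm <- c(-e[2], e[1])           # inward normal
    denom <- sum(nrm * d)
    num <- sum(nrm * (p1 - a))
    if (abs(denom) < 1e-12) {
      if (num < 0) return(0)        # parallel and outside
    } else {
      t <- -num / denom
      if (denom > 0) t0 <- max(t0, t) else t1 <- min(t1, t)
      if (t0 > t1) return(0)
    }
  }
  (t1 - t0) * sqrt(sum(d^2))
}

#' Road density within a bear-year home range
#'
#' Builds the 100% MCP over a bear-year's screened relocations, clips the
#' road network to it, and returns km of road per km^2 of range.
#'
#' @param x,y Relocation coordinates (m) of one bear-year.
#' @param roads A `road_network`.
#' @return List with `polygon` (hull vertices), `area_km2`, `road_km` and
#'   `density` (km/km^2).
#' @export
home_range_road_density <- function(x, y, roads) {
  poly <- mcp_polygon(x, y)
  area_km2 <- polygon_area(poly) / 1e6
  segs <- road_segments(roads)
  total_m <- 0
  for (i in seq_len(nrow(segs))) {
    total_m <- total_m + clip_segment_length(segs[i, 1:2], segs[i, 3:4], poly)
  }
  list(polygon = poly, area_km2 = area_km2, road_km = total_m / 1000,
       density = (total_m / 1000) / area_km2)
}
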