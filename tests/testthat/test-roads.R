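# Road-network geometry: grid generation, point-to-road distance, MCP home
# ranges, and road density.

test_that("grid generator produces hand-computable layouts", {
  # degenerate: spacing equal to the arena leaves one line per direction
  g1 <- generate_roads(1000, 1000)
  expect_length(g1$polylines, 2)
  expect_equal(road_length(g1), 2000)

  # 1 km arena at 500 m spacing: lines at 250 and 750 m in each direction
  g2 <- generate_roads(500, 1000)
  expect_length(g2$polylines, 4)
  expect_equal(road_length(g2), 4000)

  expect_identical(generate_roads(500, 1000), generate_roads(500, 1000))
  expect_error(generate_roads(0, 1000), "positive")
  expect_error(generate_roads(-5, 1000), "positive")
})

test_that("distance to road handles on-road, perpendicular and empty cases", {
  axis_road <- road_network(list(cbind(c(-1000, 1000), c(0, 0))))
  expect_equal(distance_to_road(0, 0, axis_road), 0)
  expect_equal(distance_to_road(0, 100, axis_road), 100)
  expect_equal(distance_to_road(c(500, -500), c(-40, 30), axis_road), c(40, 30))
  # beyond the segment end the nearest point is the endpoint
  expect_equal(distance_to_road(1300, 400, axis_road), 500)
  expect_error(distance_to_road(0, 0, list()), "road_network")
})

test_that("distance to road is invariant under rigid translation", {
  set.seed(42)
  roads <- generate_roads(400, 2000)
  x <- runif(50, 0, 2000); y <- runif(50, 0, 2000)
  d0 <- distance_to_road(x, y, roads)
  shift <- c(12345, -6789)
  roads2 <- road_network(lapply(roads$polylines, function(p)
    cbind(p[, 1] + shift[1], p[, 2] + shift[2])))
  d1 <- distance_to_road(x + shift[1], y + shift[2], roads2)
  expect_equal(d0, d1, tolerance = 1e-9)
})

test_that("MCP area matches an exhaustive hull oracle on random clouds", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:20, 1)
    x <- runif(n, 0, 1000); y <- runif(n, 0, 1000)
    poly <- mcp_polygon(x, y)
    expect_equal(polygon_area(poly), brute_force_hull_area(x, y),
                 tolerance = 1e-9)
  }
})

test_that("MCP rejects degenerate inputs", {
  expect_error(mcp_polygon(c(0, 1), c(0, 1)), "at least 3")
  expect_error(mcp_polygon(c(0, 1, 2, 3), c(0, 1, 2, 3)), "collinear")
})

test_that("road density recovers the unit case and empty intersections", {
  # 1 km x 1 km range crossed by a single straight road: 1 km / 1 km^2
  sq_x <- c(0, 1000, 1000, 0); sq_y <- c(0, 0, 1000, 1000)
  one_road <- road_network(list(cbind(c(-500, 1500), c(500, 500))))
  hr <- home_range_road_density(sq_x, sq_y, one_road)
  expect_equal(hr$area_km2, 1)
  expect_equal(hr$road_km, 1)
  expect_equal(hr$density, 1)

  far_road <- road_network(list(cbind(c(5000, 6000), c(5000, 5000))))
  expect_equal(home_range_road_density(sq_x, sq_y, far_road)$density, 0)
})
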