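track_from_ll <- function(lat, lon) {
  data.frame(lat = lat, lon = lon)
}

test_that("path length sums geodesics and is zero for a single fix", {
  expect_equal(path_length_km(track_from_ll(54.3, -6.5)), 0)
  out <- track_from_ll(c(54.3, 54.31, 54.3), c(-6.5, -6.49, -6.5))
  d1 <- geosphere::distGeo(c(-6.5, 54.3), c(-6.49, 54.31))
  expect_equal(path_length_km(out), 2 * d1 / 1000)
})

test_that("geodesic lengths agree with an independent haversine within 0.5%", {
  set.seed(6)
  lat1 <- runif(100, 53, 55)
  lon1 <- runif(100, -8, -6)
  brg <- runif(100, 0, 2 * pi)
  dist <- runif(100, 100, 50000)
  lat2 <- lat1 + dist * cos(brg) / 111320
  lon2 <- lon1 + dist * sin(brg) / (111320 * cos(lat1 * pi / 180))
  geo <- geosphere::distGeo(cbind(lon1, lat1), cbind(lon2, lat2))
  hav <- haversine_m(lat1, lon1, lat2, lon2)
  expect_lt(max(abs(geo / hav - 1)), 0.005)
})

test_that("trimming removes exactly the constructed outliers", {
  set.seed(7)
  inner <- cbind(runif(95), runif(95))
  outer <- cbind(10000 + runif(5), 10000 + runif(5))
  pts <- rbind(inner, outer)[sample(100), ]
  kept <- trim_outliers(pts, 0.05)
  expect_equal(nrow(kept), 95)
  expect_true(all(kept[, 1] < 100))
  # brute-force oracle: drop the 5 largest centroid distances
  ctr <- colMeans(pts)
  d <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  keep_idx <- order(d)[1:95]
  expect_setequal(kept[, 1], pts[keep_idx, 1])
})

test_that("trimming edge cases: zero fraction, identical points, bad fraction", {
  pts <- cbind(rnorm(50), rnorm(50))
  expect_identical(trim_outliers(pts, 0), pts)
  same <- matrix(1, 40, 2)
  kept <- trim_outliers(same, 0.05)
  expect_equal(nrow(kept), 38)
  expect_true(all(kept == 1))
  expect_error(trim_outliers(pts, 0.5), "fraction")
  expect_error(trim_outliers(pts, -0.1), "fraction")
})

test_that("MCP of the unit square is exact and the 360-gon matches the closed form", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  hr <- mcp_area(sq, level = 1)
  expect_equal(hr$area_km2, 1e-6)
  theta <- 2 * pi * (0:359) / 360
  ngon <- cbind(100 * cos(theta), 100 * sin(theta))
  hr2 <- mcp_area(ngon, level = 1)
  closed_form <- (360 / 2) * 100^2 * sin(2 * pi / 360)
  expect_equal(hr2$area_km2 * 1e6, closed_form, tolerance = 1e-9)
  expect_equal(hr2$area_km2 * 1e6, pi * 100^2, tolerance = 1e-3)
})

test_that("collinear points flag a degenerate MCP", {
  line <- cbind(1:10, 2 * (1:10))
  hr <- mcp_area(line, level = 1)
  expect_true(hr$degenerate)
  expect_equal(hr$area_km2, 0)
})

test_that("adding a point never shrinks the untrimmed MCP", {
  set.seed(8)
  pts <- cbind(rnorm(40, sd = 50), rnorm(40, sd = 50))
  a0 <- mcp_area(pts, level = 1)$area_km2
  for (r in 1:10) {
    pts2 <- rbind(pts, c(rnorm(1, sd = 80), rnorm(1, sd = 80)))
    expect_gte(mcp_area(pts2, level = 1)$area_km2, a0 - 1e-15)
  }
})

test_that("untrimmed MCP area is at least the MCP95 area", {
  set.seed(9)
  pts <- cbind(rnorm(200, sd = 100), rnorm(200, sd = 100))
  expect_gte(mcp_area(pts, level = 1)$area_km2,
             mcp_area(pts, level = 0.95)$area_km2)
})

test_that("kernel range splits across distant clusters and stays below the MCP", {
  set.seed(10)
  c1 <- cbind(rnorm(500, 0, 20), rnorm(500, 0, 20))
  c2 <- cbind(rnorm(500, 1000, 20), rnorm(500, 0, 20))
  pts <- rbind(c1, c2)
  kde <- kde_home_range(pts, bandwidth = 15, trim = 0, grid_n = 250)
  expect_gte(length(kde$polygons), 2)
  expect_lt(kde$area_km2, mcp_area(pts, level = 1)$area_km2)
  expect_gte(kde$mass_inside, 0.945)
  expect_lte(kde$mass_inside, 0.96)
})

test_that("kernel-range area is stable under grid refinement", {
  set.seed(11)
  pts <- cbind(rnorm(2000, 0, 100), rnorm(2000, 0, 100))
  a1 <- kde_home_range(pts, bandwidth = 10, trim = 0, grid_n = 200)$area_km2
  a2 <- kde_home_range(pts, bandwidth = 10, trim = 0, grid_n = 400)$area_km2
  expect_lt(abs(a2 / a1 - 1), 0.02)
})

test_that("identical points flag a degenerate kernel range", {
  hr <- kde_home_range(matrix(5, 50, 2), trim = 0)
  expect_true(hr$degenerate)
})

proximity_track <- function(e, n, source, epsg = 32629) {
  new_track(seq_along(e) - 1, e, n, source, epsg)
}

test_that("time weighting: 40 Hz samples vs hourly fixes", {
  cfg <- sim_config(field_grid = c(2, 2))
  ls <- generate_landscape(cfg)
  centre <- colMeans(ls$polygons[[1]]$ring[1:4, ])
  # 3600 dead-reckoned samples inside one field: 90 s
  dr <- proximity_track(rep(centre[1], 3600), rep(centre[2], 3600),
                        "dead_reckoned")
  pb <- proximity_times(dr, ls, radius_m = 20, fs = 40)
  expect_equal(pb$time_s[pb$class == "field"], 90)
  expect_equal(pb$proportion[pb$class == "field"], 1)
  # 7 hourly GPS fixes within a hedge buffer: 7 h
  hedge <- Filter(function(p) p$class == "hedge", ls$polygons)[[1]]
  hc <- colMeans(hedge$ring[1:4, ])
  g <- proximity_track(rep(hc[1], 7), rep(hc[2], 7), "gps")
  pg <- proximity_times(g, ls, radius_m = 20)
  expect_equal(pg$time_s[pg$class == "hedge"], 7 * 3600)
})

test_that("the 20 m rule is a hard threshold between classes", {
  cfg <- sim_config(field_grid = c(2, 2))
  ls <- generate_landscape(cfg)
  hedge <- Filter(function(p) p$class == "hedge", ls$polygons)[[1]]
  # a point inside a field, 25 m east of the vertical hedge strip
  x <- max(hedge$ring[, 1]) + 25
  y <- mean(hedge$ring[, 2])
  tr <- proximity_track(x, y, "gps")
  pb <- proximity_times(tr, ls, radius_m = 20)
  expect_equal(pb$n_points[pb$class == "field"], 1)
  expect_equal(pb$n_points[pb$class == "hedge"], 0)
})

test_that("per-class time never exceeds the tracked total, and a disjoint partition adds up", {
  nt <- quick_night()
  dr <- dead_reckon(nt$stream, nt$fixes)
  pb <- proximity_times(dr, nt$landscape, radius_m = 20, fs = nt$stream$fs)
  expect_true(all(pb$time_s <= attr(pb, "total_time_s") + 1e-9))
  expect_true(all(pb$proportion >= 0 & pb$proportion <= 1))
  # radius 0 on fields: the field polygons tile the block disjointly, so
  # the summed field time equals the time inside the union of fields
  fields_only <- nt$landscape
  fields_only$polygons <- Filter(function(p) p$class == "field",
                                 fields_only$polygons)
  counts <- 0
  for (p in fields_only$polygons) {
    counts <- counts + sum(points_in_ring(cbind(dr$easting, dr$northing),
                                          p$ring))
  }
  inside_any <- rep(FALSE, nrow(dr))
  for (p in fields_only$polygons) {
    inside_any <- inside_any | points_in_ring(cbind(dr$easting, dr$northing),
                                              p$ring)
  }
  # tiles share only boundaries, which have measure zero for real tracks
  expect_equal(counts, sum(inside_any))
})

test_that("mixed-source tracks are rejected", {
  tr <- proximity_track(1:3, 1:3, "gps")
  attr(tr, "source") <- c("gps", "dead_reckoned")
  expect_error(proximity_times(tr, generate_landscape(sim_config())),
               "per source")
})
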