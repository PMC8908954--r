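test_that("path integration obeys the speed model and axis convention", {
  n <- 3600 * 40
  dt <- 1 / 40
  m <- speed_model(2, 0)
  still <- integrate_path(rep(0, 100), rep(45, 100), m, c(5, 7), dt)
  expect_true(all(still[, "easting"] == 5 & still[, "northing"] == 7))
  north <- integrate_path(rep(0.25, n), rep(0, n), m, c(0, 0), dt)
  expect_equal(unname(north[n, ]), c(0, 1800), tolerance = 1e-9)
  east <- integrate_path(rep(0.25, n), rep(90, n), m, c(0, 0), dt)
  expect_equal(unname(east[n, "easting"]), 1800, tolerance = 1e-9)
  expect_lt(abs(east[n, "northing"]), 1e-6)
  # below-ground samples contribute no displacement
  below <- rep(c(FALSE, TRUE), each = n / 2)
  half <- integrate_path(rep(0.25, n), rep(0, n), m, c(0, 0), dt, below)
  expect_equal(unname(half[n, "northing"]), 900, tolerance = 1e-9)
  expect_error(integrate_path(1:5, 1:4, m, dt = dt), "length")
})

# a tiny self-consistent scene: constant speed northwards, fixes on the path
.toy_scene <- function(m_true = 2, vedba = 0.2, n_h = 3) {
  fs <- 40
  n <- n_h * 3600 * fs + 1  # inclusive endpoint so the last fix is in span
  time_s <- (seq_len(n) - 1) / fs
  ved <- rep(vedba, n)
  hd <- rep(0, n)
  speed <- m_true * vedba
  fix_t <- seq(0, n_h * 3600, by = 3600)
  fix_t[1] <- 0
  north <- speed * fix_t
  ll <- utm_unproject(rep(500000, length(fix_t)), 6000000 + north)
  fixes <- data.frame(time_s = fix_t, lat = ll[, "lat"], lon = ll[, "lon"])
  list(vedba = ved, heading = hd, time_s = time_s, fixes = fixes, fs = fs)
}

test_that("calibration at a fixed point leaves the gradient unchanged in one iteration", {
  sc <- .toy_scene(m_true = 2)
  fit <- calibrate_speed_model(sc$vedba, sc$heading, sc$time_s, sc$fixes,
                               initial = speed_model(2), fs = sc$fs)
  expect_equal(fit$m, 2, tolerance = 1e-9)
  expect_equal(attr(fit, "iterations"), 1L)
})

test_that("calibration rescales a wrong nominal gradient onto the GPS displacements", {
  sc <- .toy_scene(m_true = 2)
  fit <- calibrate_speed_model(sc$vedba, sc$heading, sc$time_s, sc$fixes,
                               initial = speed_model(0.7), fs = sc$fs)
  expect_equal(fit$m, 2, tolerance = 1e-6)
})

test_that("doubling VeDBA halves the fitted gradient", {
  sc <- .toy_scene(m_true = 2)
  f1 <- calibrate_speed_model(sc$vedba, sc$heading, sc$time_s, sc$fixes,
                              initial = speed_model(1), fs = sc$fs)
  f2 <- calibrate_speed_model(2 * sc$vedba, sc$heading, sc$time_s, sc$fixes,
                              initial = speed_model(1), fs = sc$fs)
  expect_equal(f2$m, f1$m / 2, tolerance = 1e-9)
})

test_that("zero VeDBA with real GPS displacement is a calibration failure", {
  sc <- .toy_scene(m_true = 2)
  expect_error(
    calibrate_speed_model(0 * sc$vedba, sc$heading, sc$time_s, sc$fixes,
                          initial = speed_model(1), fs = sc$fs),
    "no speed signal"
  )
})

test_that("correction is the identity for a zero-residual track", {
  sc <- .toy_scene(m_true = 2)
  path <- integrate_path(sc$vedba, sc$heading, speed_model(2),
                         c(500000, 6000000), 1 / sc$fs)
  # first sample displacement offsets the start; rebuild track from start
  dr <- new_track(sc$time_s, path[, 1], path[, 2] - path[1, 2] + 6000000,
                  "dead_reckoned", 32629)
  out <- gps_correct_track(dr, sc$fixes)
  # residuals are sub-mm: dominated by the WGS84 round-trip of the fixes
  expect_lt(max(abs(out$easting - dr$easting)), 1e-3)
  expect_lt(max(abs(out$northing - dr$northing)), 1e-3)
})

test_that("a uniform drift is absorbed linearly: midpoint gets half the end residual", {
  fs <- 1
  n <- 1001
  time_s <- seq(0, 1000)
  # true position fixed at origin; DR drifts east at 0.1 m/s
  dr <- new_track(time_s, 600000 + 0.1 * time_s, 6000000 + 0 * time_s,
                  "dead_reckoned", 32629)
  ll <- utm_unproject(c(600000, 600000), c(6000000, 6000000))
  fixes <- data.frame(time_s = c(0, 1000), lat = ll[, "lat"], lon = ll[, "lon"])
  out <- gps_correct_track(dr, fixes)
  expect_lt(max(attr(out, "anchor_error_m")), 1e-6)
  mid <- which(time_s == 500)
  # drift at the midpoint is 50 m; the end residual is -100 m, half applied
  expect_equal(out$easting[mid], 600000, tolerance = 1e-9)
  expect_lt(max(abs(out$easting - 600000)), 1e-4)
})

test_that("fixes outside the track span are skipped with a warning", {
  dr <- new_track(seq(0, 100), rep(600000, 101), rep(6000000, 101),
                  "dead_reckoned", 32629)
  ll <- utm_unproject(c(600000, 600000), c(6000000, 6000000))
  fixes <- data.frame(time_s = c(50, 500), lat = ll[, "lat"], lon = ll[, "lon"])
  expect_warning(out <- gps_correct_track(dr, fixes), "outside the track")
  expect_equal(length(attr(out, "anchor_error_m")), 1)
})

test_that("end-to-end dead-reckoning anchors through every fix and beats GPS interpolation", {
  nt <- quick_night()
  dr <- dead_reckon(nt$stream, nt$fixes)
  expect_equal(track_source(dr), "dead_reckoned")
  expect_lt(max(attr(dr, "anchor_error_m")), 1e-6)
  span <- range(nt$fixes$time_s)
  sel <- dr$time_s >= span[1] & dr$time_s <= span[2]
  rms_dr <- track_rmse(dr[sel, ], nt$truth)
  gi <- gps_interpolate(nt$fixes, dr$time_s[sel])
  rms_gps <- track_rmse(gi, nt$truth, time_s = dr$time_s[sel])
  expect_lt(rms_dr, rms_gps)
  # corrected DR cannot be shorter than the straight-line GPS polyline
  expect_gte(path_length_km(dr), path_length_km(gps_track(nt$fixes)))
})

test_that("a night without fixes returns an unanchored track", {
  nt <- quick_night()
  empty <- nt$fixes[0, ]
  dr <- dead_reckon(nt$stream, empty)
  expect_equal(track_source(dr), "dead_reckoned_unanchored")
  expect_gt(nrow(dr), 0)
})

test_that("an all-underground record yields an empty track", {
  cfg <- quick_cfg(seed = 55)$sim
  cfg$emergence_h <- cfg$night_end_h
  cfg$return_h <- cfg$night_end_h
  tr <- simulate_true_track(cfg, 1, 1)
  st <- render_sensor_streams(tr, cfg)
  dr <- dead_reckon(st, data.frame(time_s = numeric(0), lat = numeric(0),
                                   lon = numeric(0)))
  expect_equal(nrow(dr), 0)
})
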