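test_that("underground segments render VeDBA below 0.1 g throughout", {
  nt <- quick_night()
  v_est <- compute_vedba(split_static_dynamic(nt$stream, 2))
  under <- !nt$truth$above
  # keep clear of bout transitions, where the 2 s static filter still
  # sees above-ground movement
  edges <- which(diff(under) != 0)
  margin <- 3 * nt$stream$fs
  for (e in edges) {
    lo <- max(1, e - margin)
    hi <- min(length(under), e + margin)
    under[lo:hi] <- FALSE
  }
  expect_gt(sum(under), 1000)
  # smoothed over a second to iron out single-sample noise
  expect_true(all(running_mean(v_est, 41)[under] < 0.1))
})

test_that("active walking renders VeDBA near the 0.25 g level", {
  nt <- quick_night()
  travel <- nt$truth$state == "travel"
  expect_gt(sum(travel), 500)
  m_ved <- mean(nt$signals$vedba[travel])
  expect_gt(m_ved, 0.2)
  expect_lt(m_ved, 0.3)
})

test_that("rendered streams are deterministic and refuse ragged time grids", {
  nt <- quick_night()
  s2 <- render_sensor_streams(nt$truth, nt$cfg$sim)
  expect_identical(nt$stream$acc, s2$acc)
  bad <- nt$truth
  bad$time_s[5] <- bad$time_s[5] + 0.1
  expect_error(render_sensor_streams(bad, nt$cfg$sim), "uniform")
})

test_that("round trip: processing recovers the generating heading and VeDBA", {
  nt <- quick_night()
  gen <- nt$stream$render_truth
  sig <- nt$signals
  ang_err <- ((sig$heading_deg - gen$heading_deg + 180) %% 360) - 180
  expect_lt(sqrt(mean(ang_err^2)), 2)            # < 2 degrees RMS
  mov <- gen$vedba_g >= 0.05
  rel <- (sig$vedba[mov] - gen$vedba_g[mov]) / gen$vedba_g[mov]
  expect_lt(sqrt(mean(rel^2)), 0.10)             # < 10% relative RMS
})

test_that("temperature relaxes towards the sett offset after entry", {
  nt <- quick_night()
  cfg <- nt$cfg$sim
  tr <- nt$truth
  # first below-ground run at the start of the night ends at emergence
  emergence <- attr(tr, "emergence_s")
  pre <- tr$time_s < emergence - 60
  post <- tr$time_s > emergence + 3 * cfg$sett_temp_tau_s &
    tr$above & tr$time_s < attr(tr, "return_s") - 60
  expect_gt(mean(nt$stream$temp_c[pre]) - mean(nt$stream$temp_c[post]),
            0.8 * cfg$sett_temp_offset_c)
  # the native channel is held between 7 Hz samples
  expect_lt(mean(nt$stream$temp_valid), 7.5 / cfg$fs + 0.01)
  expect_gt(mean(nt$stream$temp_valid), 6.5 / cfg$fs)
})

test_that("gps sampling is exact with zero error and respects the schedule", {
  cfg0 <- quick_cfg(seed = 21)$sim
  cfg0$sigma_gps_m <- 0
  tr <- simulate_true_track(cfg0, 1, 1)
  fx <- sample_gps(tr, cfg0)
  en <- utm_project(fx$lat, fx$lon, cfg0$epsg)
  idx <- round((fx$time_s - tr$time_s[1]) * cfg0$fs) + 1
  # sub-mm: the only error left is the WGS84 projection round-trip
  expect_lt(max(abs(en[, "easting"] - tr$easting[idx])), 1e-3)
  expect_lt(max(abs(en[, "northing"] - tr$northing[idx])), 1e-3)
  sched <- attr(fx, "schedule")
  expect_true(all(!sched$withheld[sched$time_s %in% fx$time_s]))
})

test_that("a fully above-ground hourly night yields inclusive-endpoint fixes", {
  cfg <- sim_config(seed = 9, night_start_h = 20.5, night_end_h = 28.5,
                    emergence_h = 20.6, return_h = 28.4,
                    emergence_jitter_min = 0, return_jitter_min = 0,
                    midnight_bout_prob = 0,
                    gps_start_h = 21, gps_end_h = 28)
  tr <- simulate_true_track(cfg, 1, 1)
  fx <- sample_gps(tr, cfg)
  expect_equal(nrow(fx), 8)  # 21:00 ... 04:00 inclusive
})

test_that("fixes during below-ground bouts are withheld", {
  nt <- quick_night()
  sched <- attr(nt$fixes, "schedule")
  tr <- nt$truth
  idx <- round((sched$time_s - tr$time_s[1]) * attr(tr, "fs")) + 1
  expect_identical(sched$withheld, !tr$above[idx])
})

test_that("gps errors are isotropic with the configured magnitude", {
  cfg <- quick_cfg(seed = 31)$sim
  errs <- numeric(0)
  landscape <- generate_landscape(cfg)
  for (r in 1:40) {
    tr <- simulate_true_track(cfg, 1, r, landscape)
    fx <- sample_gps(tr, cfg)
    en <- utm_project(fx$lat, fx$lon, cfg$epsg)
    idx <- round((fx$time_s - tr$time_s[1]) * cfg$fs) + 1
    errs <- c(errs, en[, "easting"] - tr$easting[idx],
              en[, "northing"] - tr$northing[idx])
  }
  # per-axis SD ~ sigma; pooled radial RMS = sigma * sqrt(2)
  expect_equal(sqrt(mean(errs^2)), cfg$sigma_gps_m, tolerance = 0.05)
})
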