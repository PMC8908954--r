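# Shared fixtures. Expensive objects are built once per test run and
# memoised in this environment.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small, fast configuration: a 2.5 h "night" with half-hourly GPS
quick_cfg <- function(seed = 7L, ...) {
  study_config(
    seed = seed,
    sim = sim_config(seed = seed,
                     n_animals = 1L, n_nights = 1L,
                     night_start_h = 21, night_end_h = 23.5,
                     emergence_h = 21.15, return_h = 23.35,
                     emergence_jitter_min = 3, return_jitter_min = 3,
                     midnight_bout_prob = 0,
                     gps_start_h = 21.5, gps_end_h = 23,
                     gps_interval_s = 1800, ...)
  )
}

quick_night <- function() {
  memo("quick_night", {
    cfg <- quick_cfg()
    nt <- simulate_night(cfg, 1, 1)
    nt$cfg <- cfg
    nt$landscape <- generate_landscape(cfg$sim)
    nt$signals <- derive_signals(nt$stream, cfg$window_s)
    nt
  })
}

# the full study at the default conditions (2 badgers x 7 nights)
full_study <- function() {
  memo("full_study", run_study(study_config(seed = 1)))
}

# 20 seeded single-night replicates at the default study conditions:
# per replicate, the fitted speed~VeDBA gradient and the sample-wise
# sett-occupancy agreement against the generating mask
calibration_replicates <- function(n_rep = 20) {
  memo("calibration_replicates", {
    cfg <- study_config(seed = 97)
    landscape <- generate_landscape(cfg$sim)
    out <- data.frame(rep = seq_len(n_rep), m_hat = NA_real_,
                      agreement = NA_real_)
    for (r in seq_len(n_rep)) {
      truth <- simulate_true_track(cfg$sim, animal = 1, night = r, landscape)
      stream <- render_sensor_streams(truth, cfg$sim)
      fixes <- sample_gps(truth, cfg$sim)
      sig <- derive_signals(stream, cfg$window_s)
      bouts <- detect_sett_occupancy(sig$vedba, stream$temp_c,
                                     fs = stream$fs, time_s = stream$time_s)
      out$agreement[r] <- mean(attr(bouts, "below_mask") == !truth$above)
      fit <- calibrate_speed_model(sig$vedba, sig$heading_deg,
                                   stream$time_s, fixes,
                                   initial = speed_model(1),
                                   fs = stream$fs,
                                   below = attr(bouts, "below_mask"),
                                   epsg = cfg$sim$epsg)
      out$m_hat[r] <- fit$m
    }
    out
  })
}

# hand-written haversine, the independent oracle for geodesic lengths
haversine_m <- function(lat1, lon1, lat2, lon2, R = 6371008.8) {
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dp <- p2 - p1
  dl <- (lon2 - lon1) * pi / 180
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

# explicit rotation-matrix oracle for the body frame (x fwd, y left, z up)
rot_body_to_world <- function(yaw_deg, pitch_deg, roll_deg) {
  Rx <- function(a) rbind(c(1, 0, 0),
                          c(0, cos(a), -sin(a)),
                          c(0, sin(a), cos(a)))
  Ry <- function(a) rbind(c(cos(a), 0, sin(a)),
                          c(0, 1, 0),
                          c(-sin(a), 0, cos(a)))
  Rz <- function(a) rbind(c(cos(a), -sin(a), 0),
                          c(sin(a), cos(a), 0),
                          c(0, 0, 1))
  d <- pi / 180
  Rz(-yaw_deg * d) %*% Ry(-pitch_deg * d) %*% Rx(roll_deg * d)
}
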