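#' Render collar sensor streams from a ground-truth track
#'
#' Produces tri-axial acceleration (g), tri-axial magnetometer readings
#' (arbitrary units) and temperature (native 7 Hz, held on the 40 Hz grid)
#' consistent with the track's speed, heading and occupancy:
#'
#' * the target VeDBA per sample is `max(0, (speed - c_true) / m_true)`
#'   plus context-dependent truncated noise (a small positive floor when
#'   underground or fidgeting above ground, zero-mean jitter when moving);
#' * the dynamic acceleration is band-limited (2-8 Hz) vector noise scaled
#'   so its per-sample magnitude equals that target, added to the gravity
#'   vector rotated by simulated pitch/roll (slow bounded noise plus a
#'   posture offset);
#' * the magnetometer is a fixed Earth field (configurable inclination,
#'   declination 0 by default) rotated into the body frame by the full
#'   heading/pitch/roll rotation;
#' * temperature follows ambient above ground and relaxes first-order
#'   towards ambient + sett offset below ground (closed-form per bout),
#'   sampled at the native 7 Hz and held on the 40 Hz grid.
#'
#' Body axes: x forward, y left, z up; a level, motionless collar reads
#' acceleration (0, 0, 1) g.
#'
#' @param track a [simulate_true_track()] result on a uniform 40 Hz grid.
#' @param config the [sim_config()] the track was generated from.
#' @return A list of class `badger_sensorstream`: `time_s`, `acc` (n x 3,
#'   g), `mag` (n x 3), `temp_c`, `temp_valid` (TRUE where a fresh native
#'   temperature sample was taken), `fs`, `temp_fs`, plus animal/night ids.
#' @export
render_sensor_streams <- function(track, config) {
  stopifnot(inherits(track, "badger_truetrack"))
  n <- nrow(track)
  fs <- config$fs
  dts <- diff(track$time_s)
  if (any(abs(dts - 1 / fs) > 1e-6)) {
    stop("track timestamps must be uniform at the sensor sample rate")
  }
  set.seed(derive_seed(config$seed, attr(track, "animal"),
                       attr(track, "night"), 2L))

  # --- target VeDBA ---------------------------------------------------
  base <- pmax(0, (track$speed_ms - config$c_true) / config$m_true)
  ctx <- ifelse(!track$above, "underground",
                ifelse(track$speed_ms > 0, "moving", "stationary"))
  eps <- numeric(n)
  for (cc in c("underground", "stationary", "moving")) {
    i <- ctx == cc
    if (!any(i)) next
    noise <- stats::rnorm(sum(i), 0, config$vedba_noise_g[[cc]])
    if (cc != "moving") noise <- abs(noise)
    eps[i] <- noise + config$vedba_floor_g[[cc]]
  }
  vedba_t <- pmax(0, base + eps)

  # --- dynamic acceleration: band-limited direction, exact magnitude ---
  bp <- signal::butter(2, c(2, 8) / (fs / 2), type = "pass")
  dir3 <- vapply(1:3, function(k) signal::filtfilt(bp, stats::rnorm(n)),
                 numeric(n))
  L <- sqrt(rowSums(dir3^2))
  L[L < 1e-9] <- 1
  dyn <- dir3 / L * vedba_t

  # --- posture: slow pitch/roll noise, clamped ------------------------
  lp <- signal::butter(2, 0.05 / (fs / 2), type = "low")
  slow <- function(sd_deg) {
    x <- signal::filtfilt(lp, stats::rnorm(n))
    x <- x / max(stats::sd(x), 1e-12) * sd_deg
    pmin(config$tilt_max_deg, pmax(-config$tilt_max_deg, x))
  }
  pitch <- config$pitch_offset_deg + slow(config$tilt_noise_deg)
  roll <- slow(config$tilt_noise_deg)
  p <- deg2rad(pitch)
  r <- deg2rad(roll)

  grav <- cbind(sin(p), sin(r) * cos(p), cos(r) * cos(p))
  acc <- grav + dyn + matrix(stats::rnorm(3 * n, 0, 0.002), ncol = 3)

  # --- collar heading: travel heading plus resting wander -------------
  # while not locomoting the collar keeps turning (grooming, on-the-spot
  # foraging); the wander is a random walk that restarts from zero at
  # every locomoting sample
  moving <- track$speed_ms > 0
  winc <- stats::rnorm(n, 0, config$rest_heading_wander_deg)
  winc[moving] <- 0
  g_cum <- cumsum(winc)
  base_off <- rep(NA_real_, n)
  base_off[moving] <- g_cum[moving]
  if (!moving[1]) base_off[1] <- 0
  wander <- g_cum - locf(base_off)
  heading_used <- track$heading_deg + wander

  # --- magnetometer ---------------------------------------------------
  incl <- deg2rad(config$mag_inclination_deg)
  dec <- deg2rad(config$mag_declination_deg)
  h <- deg2rad(heading_used)
  # world frame (north, west, up); field points `dec` east of true north
  wx <- cos(incl) * cos(h - dec)
  wy <- cos(incl) * sin(h - dec)
  wz <- -sin(incl)
  # Ry(p) then Rx(-r): world field into the tilted body frame
  vx <- cos(p) * wx + sin(p) * wz
  vy <- wy
  vz <- -sin(p) * wx + cos(p) * wz
  mx <- vx
  my <- cos(r) * vy + sin(r) * vz
  mz <- -sin(r) * vy + cos(r) * vz
  mag <- config$mag_field * cbind(mx, my, mz) +
    matrix(stats::rnorm(3 * n, 0, 0.003 * config$mag_field), ncol = 3)

  # --- temperature at native rate, relaxing per occupancy bout --------
  t_nat <- seq(track$time_s[1], track$time_s[n], by = 1 / config$temp_fs)
  idx40 <- pmin(n, pmax(1L, round((t_nat - track$time_s[1]) * fs) + 1L))
  target <- ifelse(track$above[idx40], config$ambient_temp_c,
                   config$ambient_temp_c + config$sett_temp_offset_c)
  runs <- rle(target)
  temp_nat <- numeric(length(t_nat))
  pos <- 1L
  t_prev <- runs$values[1]  # start equilibrated to the first context
  for (k in seq_along(runs$lengths)) {
    len <- runs$lengths[k]
    seg <- pos:(pos + len - 1L)
    el <- t_nat[seg] - t_nat[seg[1]]
    temp_nat[seg] <- runs$values[k] +
      (t_prev - runs$values[k]) * exp(-el / config$sett_temp_tau_s)
    t_prev <- temp_nat[seg[len]]
    pos <- pos + len
  }
  temp_nat <- temp_nat + stats::rnorm(length(temp_nat), 0, 0.05)
  hold <- findInterval(track$time_s + 1e-9, t_nat)
  hold[hold < 1L] <- 1L
  temp_c <- temp_nat[hold]
  temp_valid <- c(TRUE, diff(hold) > 0)

  structure(
    list(time_s = track$time_s,
         acc = unname(acc), mag = unname(mag),
         temp_c = temp_c, temp_valid = temp_valid,
         fs = fs, temp_fs = config$temp_fs,
         animal = attr(track, "animal"), night = attr(track, "night"),
         epsg = config$epsg, base_date = config$base_date,
         # generating values, kept for round-trip validation only
         render_truth = list(heading_deg = heading_used %% 360,
                             pitch_deg = pitch, roll_deg = roll,
                             vedba_g = vedba_t)),
    class = "badger_sensorstream"
  )
}

#' @export
print.badger_sensorstream <- function(x, ...) {
  cat(sprintf("<badger_sensorstream> %d samples at %g Hz (%.2f h), temp %g Hz\n",
              length(x$time_s), x$fs,
              (x$time_s[length(x$time_s)] - x$time_s[1]) / 3600, x$temp_fs))
  invisible(x)
}

#' Sample GPS fixes from a ground-truth track
#'
#' Fixes are scheduled every `gps_interval_s` between `gps_start_h` and
#' `gps_end_h` and observed as the true position plus isotropic Gaussian
#' error. Scheduled fixes falling in a below-ground interval are withheld
#' (no sky view inside the sett); the full schedule, with the withheld
#' flag, is kept as the `schedule` attribute.
#'
#' @param track a `badger_truetrack`.
#' @param config the matching [sim_config()].
#' @return A data.frame of class `badger_gpsfixes` with columns `time_s`,
#'   `time_iso`, `lat`, `lon`, `error_m`.
#' @export
sample_gps <- function(track, config) {
  stopifnot(inherits(track, "badger_truetrack"))
  set.seed(derive_seed(config$seed, attr(track, "animal"),
                       attr(track, "night"), 3L))
  fs <- config$fs
  sched <- seq(config$gps_start_h * 3600, config$gps_end_h * 3600,
               by = config$gps_interval_s)
  sched <- sched[sched >= track$time_s[1] &
                 sched <= track$time_s[nrow(track)]]
  if (length(sched) == 0) {
    stop("GPS schedule does not intersect the track time span")
  }
  idx <- round((sched - track$time_s[1]) * fs) + 1L
  ok <- track$above[idx]
  e <- track$easting[idx][ok] + stats::rnorm(sum(ok), 0, config$sigma_gps_m)
  nn <- track$northing[idx][ok] + stats::rnorm(sum(ok), 0, config$sigma_gps_m)
  ll <- utm_unproject(e, nn, config$epsg)
  night <- attr(track, "night")
  t_posix <- as.POSIXct(config$base_date, tz = "UTC") +
    (night - 1) * 86400 + sched[ok]
  out <- data.frame(
    time_s = sched[ok],
    time_iso = format(t_posix, "%Y-%m-%dT%H:%M:%SZ"),
    lat = ll[, "lat"],
    lon = ll[, "lon"],
    error_m = config$sigma_gps_m,
    stringsAsFactors = FALSE
  )
  structure(out,
            class = c("badger_gpsfixes", "data.frame"),
            schedule = data.frame(time_s = sched, withheld = !ok),
            animal = attr(track, "animal"), night = night,
            epsg = config$epsg)
}
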