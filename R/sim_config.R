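#' Simulation configuration for the synthetic badger study
#'
#' Bundles every parameter of the synthetic-data generator: the nightly
#' schedule, the behaviour model driving speeds and headings, the true
#' speed~VeDBA relation the sensors are rendered from, GPS sampling, the
#' sett temperature response, and the landscape geometry. Defaults emulate
#' the field regime this package targets: two collared badgers tracked for
#' seven nights over pasture enclosed by hedgerows, with hourly GPS fixes
#' between 21:00 and 04:00 and collar sensors at 40 Hz (temperature 7 Hz).
#'
#' @param seed integer root seed; all per-night randomness is derived from it.
#' @param n_animals,n_nights study size (defaults 2 x 7).
#' @param night_start_h,night_end_h simulated window, in clock hours from
#'   midnight of the night's first day (defaults 20:00 to 05:00, i.e. 29).
#' @param emergence_h,return_h nominal sett-exit and sett-return times
#'   (clock hours); each night they are jittered by the corresponding
#'   `*_jitter_min` (minutes, 1 SD).
#' @param midnight_bout_prob,midnight_bout_mean_min probability and mean
#'   duration of an intermittent below-ground bout during the night.
#' @param fs,temp_fs sensor sample rates (Hz): accelerometer/magnetometer
#'   and the slower temperature channel.
#' @param m_true,c_true gradient (m s^-1 per g) and intercept (m s^-1) of
#'   the speed~VeDBA relation the sensors are generated from.
#' @param sigma_heading_deg SD of the per-sample wrapped-normal heading
#'   increment (degrees at 40 Hz); controls track tortuosity.
#' @param rest_heading_wander_deg extra per-sample collar-heading wander
#'   (degrees) while the animal is not locomoting: the neck collar keeps
#'   turning with grooming and on-the-spot foraging even though the body
#'   goes nowhere, so resting VeDBA carries no coherent travel direction.
#' @param state_dwell_s mean dwell time (s) per behaviour state.
#' @param state_speed_ms mean speed (m s^-1) per behaviour state.
#' @param speed_cv coefficient of variation of second-to-second speed.
#' @param gps_interval_s GPS schedule interval (s; must be a multiple of
#'   the 40 Hz sample interval).
#' @param gps_start_h,gps_end_h first and last scheduled fix (clock hours).
#' @param sigma_gps_m isotropic Gaussian GPS error (m, 1 SD per axis).
#' @param ambient_temp_c,sett_temp_offset_c,sett_temp_tau_s night ambient
#'   temperature, the warmer offset inside the sett, and the first-order
#'   time constant of the collar sensor's relaxation towards it. The
#'   default tau (600 s) makes the recorded change over 30 min roughly
#'   equal the full offset.
#' @param mag_inclination_deg,mag_declination_deg,mag_field Earth magnetic
#'   field model: fixed vector with the given inclination (positive down),
#'   declination (0 keeps magnetic = geographic north) and intensity
#'   (arbitrary units; heading is calibration-free).
#' @param pitch_offset_deg,tilt_noise_deg,tilt_max_deg collar posture:
#'   mean pitch offset plus slowly varying pitch/roll noise, clamped.
#' @param vedba_noise_g,vedba_floor_g per-context VeDBA noise SD and
#'   positive floor (g): `underground`, `stationary` (above ground, not
#'   moving: grooming/alert fidgeting), `moving`.
#' @param field_grid,field_size_m,hedge_width_m landscape: grid of square
#'   fields separated by hedge strips.
#' @param origin_lat,origin_lon geographic position of the main sett
#'   (landscape centre); defaults sit in rural County Down, inside UTM 29N.
#' @param epsg projected CRS for all planar work (default EPSG:32629).
#' @param base_date calendar date of night 1 (used for ISO timestamps).
#'
#' @return A list of class `badger_simconfig`.
#' @export
sim_config <- function(seed = 1L,
                       n_animals = 2L,
                       n_nights = 7L,
                       night_start_h = 20,
                       night_end_h = 29,
                       emergence_h = 20.83,
                       return_h = 27.75,
                       emergence_jitter_min = 15,
                       return_jitter_min = 15,
                       midnight_bout_prob = 0.7,
                       midnight_bout_mean_min = 25,
                       fs = 40,
                       temp_fs = 7,
                       m_true = 2.0,
                       c_true = 0.0,
                       sigma_heading_deg = 0.5,
                       rest_heading_wander_deg = 6,
                       state_dwell_s = c(stationary = 40, forage = 70, travel = 40),
                       state_speed_ms = c(stationary = 0, forage = 0.26, travel = 0.44),
                       speed_cv = 0.25,
                       gps_interval_s = 3600,
                       gps_start_h = 21,
                       gps_end_h = 28,
                       sigma_gps_m = 10,
                       ambient_temp_c = 8,
                       sett_temp_offset_c = 4,
                       sett_temp_tau_s = 600,
                       mag_inclination_deg = 67,
                       mag_declination_deg = 0,
                       mag_field = 1,
                       pitch_offset_deg = 5,
                       tilt_noise_deg = 4,
                       tilt_max_deg = 15,
                       vedba_noise_g = c(underground = 0.008, stationary = 0.012, moving = 0.02),
                       vedba_floor_g = c(underground = 0.005, stationary = 0.01, moving = 0),
                       field_grid = c(5L, 5L),
                       field_size_m = 160,
                       hedge_width_m = 4,
                       origin_lat = 54.35,
                       origin_lon = -6.5,
                       epsg = 32629,
                       base_date = as.Date("2024-03-01")) {
  cfg <- as.list(environment())
  stopifnot(
    fs > 0, temp_fs > 0,
    m_true > 0, c_true >= 0,
    sigma_heading_deg >= 0, speed_cv >= 0,
    all(state_dwell_s > 0), all(state_speed_ms >= 0),
    sigma_gps_m >= 0, sett_temp_tau_s > 0,
    n_animals >= 1, n_nights >= 1,
    night_end_h > night_start_h,
    return_h > emergence_h,
    midnight_bout_prob >= 0, midnight_bout_prob <= 1,
    field_size_m > 0
  )
  if (any(field_grid < 1)) stop("field grid dimensions must be >= 1x1")
  if (gps_interval_s <= 0 || abs(gps_interval_s * fs - round(gps_interval_s * fs)) > 1e-9) {
    stop("GPS interval must be a positive multiple of the sensor sample interval")
  }
  for (nm in c("vedba_noise_g", "vedba_floor_g")) {
    v <- cfg[[nm]]
    if (!all(c("underground", "stationary", "moving") %in% names(v)) || any(v < 0)) {
      stop(nm, " must name non-negative underground/stationary/moving values")
    }
  }
  class(cfg) <- "badger_simconfig"
  cfg
}

#' @export
print.badger_simconfig <- function(x, ...) {
  cat("<badger_simconfig>\n")
  cat(sprintf("  study: %d animal(s) x %d night(s), seed %d\n",
              x$n_animals, x$n_nights, x$seed))
  cat(sprintf("  speed~VeDBA truth: m = %.2f m/s per g, c = %.2f m/s\n",
              x$m_true, x$c_true))
  cat(sprintf("  GPS: every %d s, sigma = %.1f m; sensors %g Hz (temp %g Hz)\n",
              x$gps_interval_s, x$sigma_gps_m, x$fs, x$temp_fs))
  invisible(x)
}
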