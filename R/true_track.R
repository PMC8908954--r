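#' Simulate one night's ground-truth badger track
#'
#' Correlated random walk on the 40 Hz sensor grid, driven by a three-state
#' behaviour chain (stationary / forage / travel) with exponential dwell
#' times, plus below-ground bouts at the start and end of the night (and,
#' with probability `midnight_bout_prob`, one intermittent bout mid-night).
#' Heading evolves as a wrapped-normal random walk; the track is confined
#' to the landscape bounding box by reflection at the edges.
#'
#' After reflection, per-sample speed and heading are recomputed from the
#' realised positions, so the returned series satisfy the dead-reckoning
#' identity exactly: position_i = start + sum_{j<=i} speed_j * dt *
#' (sin h_j, cos h_j), with speed 0 wherever the state is stationary or
#' underground.
#'
#' @param config a [sim_config()].
#' @param animal,night 1-based indices; they (with the root seed) determine
#'   the night's private random stream.
#' @param landscape optional pre-built [generate_landscape()] output (it is
#'   deterministic, so passing it is purely an optimisation).
#' @return A data.frame of class `badger_truetrack` with columns `time_s`
#'   (seconds from midnight of the night's first day), `easting`,
#'   `northing` (projected m), `speed_ms`, `heading_deg`, `state`, `above`.
#'   Attributes carry the animal/night ids, sample rate, EPSG and the
#'   emergence/return times actually drawn.
#' @export
simulate_true_track <- function(config, animal = 1L, night = 1L,
                                landscape = NULL) {
  stopifnot(inherits(config, "badger_simconfig"))
  if (is.null(landscape)) landscape <- generate_landscape(config)
  set.seed(derive_seed(config$seed, animal, night, 1L))

  fs <- config$fs
  dt <- 1 / fs
  t0 <- config$night_start_h * 3600
  t1 <- config$night_end_h * 3600
  n <- round((t1 - t0) * fs)
  time_s <- t0 + (seq_len(n) - 1) * dt
  nsec <- ceiling((t1 - t0))

  emergence <- config$emergence_h * 3600 +
    stats::rnorm(1, 0, config$emergence_jitter_min * 60)
  emergence <- min(max(emergence, t0), t1)
  sett_return <- config$return_h * 3600 +
    stats::rnorm(1, 0, config$return_jitter_min * 60)
  sett_return <- min(max(sett_return, emergence), t1)

  # behaviour chain at 1 s resolution via dwell sampling
  states <- c("stationary", "forage", "travel")
  route <- rbind(stationary = c(0, 0.75, 0.25),
                 forage     = c(0.8, 0, 0.2),
                 travel     = c(0.6, 0.4, 0))
  dwell <- config$state_dwell_s[states]
  state1 <- character(nsec)
  pos <- 1L
  cur <- "stationary"
  while (pos <= nsec) {
    len <- max(1L, as.integer(round(stats::rexp(1, 1 / dwell[[cur]]))))
    state1[pos:min(nsec, pos + len - 1L)] <- cur
    pos <- pos + len
    cur <- sample(states, 1, prob = route[cur, ])
  }

  sec_time <- t0 + seq_len(nsec) - 1
  under <- sec_time < emergence | sec_time >= sett_return
  if (stats::runif(1) < config$midnight_bout_prob) {
    dur <- min(3600, max(300, stats::rexp(1, 1 / (config$midnight_bout_mean_min * 60))))
    lo <- emergence + 3600
    hi <- sett_return - 3600 - dur
    if (hi > lo) {
      b0 <- stats::runif(1, lo, hi)
      under <- under | (sec_time >= b0 & sec_time < b0 + dur)
    }
  }
  state1[under] <- "underground"

  base <- config$state_speed_ms
  sp1 <- numeric(nsec)
  moving1 <- state1 %in% c("forage", "travel")
  sp1[moving1] <- base[state1[moving1]] *
    pmax(0, stats::rnorm(sum(moving1), 1, config$speed_cv))

  state <- rep(state1, each = fs)[seq_len(n)]
  speed <- rep(sp1, each = fs)[seq_len(n)]
  speed <- running_mean(speed, fs + 1)
  moving <- state %in% c("forage", "travel")
  speed[!moving] <- 0

  h0 <- stats::runif(1, 0, 360)
  heading <- h0 + cumsum(stats::rnorm(n, 0, config$sigma_heading_deg))

  e <- landscape$sett[["easting"]] + cumsum(speed * dt * sin(deg2rad(heading)))
  nn <- landscape$sett[["northing"]] + cumsum(speed * dt * cos(deg2rad(heading)))
  bb <- landscape$bbox
  e <- fold_reflect(e, bb[["xmin"]] + 5, bb[["xmax"]] - 5)
  nn <- fold_reflect(nn, bb[["ymin"]] + 5, bb[["ymax"]] - 5)

  # re-derive speed/heading from realised (reflected) positions so the
  # integration identity holds to machine precision
  de <- diff(e)
  dn <- diff(nn)
  d <- sqrt(de^2 + dn^2)
  speed_f <- c(0, d * fs)
  heading_f <- rep(NA_real_, n)
  step_moving <- c(FALSE, d > 0)
  heading_f[step_moving] <- rad2deg(atan2(de, dn))[step_moving[-1]]
  first_ok <- which(!is.na(heading_f))[1]
  if (is.na(first_ok)) {
    heading_f[] <- h0
  } else {
    heading_f[1] <- heading_f[first_ok]
    heading_f <- locf(heading_f)
  }
  heading_f <- heading_f %% 360

  out <- data.frame(
    time_s = time_s,
    easting = e,
    northing = nn,
    speed_ms = speed_f,
    heading_deg = heading_f,
    state = state,
    above = state != "underground",
    stringsAsFactors = FALSE
  )
  structure(out,
            class = c("badger_truetrack", "data.frame"),
            animal = animal, night = night, fs = fs,
            epsg = config$epsg,
            sett = landscape$sett,
            emergence_s = emergence, return_s = sett_return,
            m_true = config$m_true, c_true = config$c_true,
            base_date = config$base_date)
}

#' True path length of a ground-truth track (km, planar)
#'
#' Direct summation of per-sample speed * dt; identical to the summed
#' step lengths by construction.
#' @param truth a `badger_truetrack`
#' @return length in km
#' @export
true_path_length_km <- function(truth) {
  fs <- attr(truth, "fs")
  sum(truth$speed_ms) / fs / 1000
}
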