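#' Split raw acceleration into static and dynamic components
#'
#' The static (gravity-dominated) component is a centred running mean per
#' axis; windows shrink symmetrically at the record edges. The dynamic
#' (movement) component is the residual, so static + dynamic reproduces
#' the raw signal to machine precision.
#'
#' @param stream a `badger_sensorstream` (or any list with `acc`, `fs`).
#' @param window_s smoothing window in seconds (default 2 s, the common
#'   biologging convention; 81 samples at 40 Hz).
#' @return A list of class `badger_derived` with `static` and `dynamic`
#'   n x 3 matrices plus the input's `time_s`, `mag` and `fs`.
#' @export
split_static_dynamic <- function(stream, window_s = 2) {
  k <- 2L * (as.integer(round(window_s * stream$fs)) %/% 2L) + 1L
  if (k < 2) stop("smoothing window must span at least 2 samples")
  n <- nrow(stream$acc)
  if (k > n) stop("smoothing window longer than the record")
  static <- vapply(1:3, function(j) running_mean(stream$acc[, j], k),
                   numeric(n))
  structure(
    list(time_s = stream$time_s,
         static = static,
         dynamic = stream$acc - static,
         mag = stream$mag,
         fs = stream$fs),
    class = "badger_derived"
  )
}

#' Vectorial dynamic body acceleration
#'
#' Per-sample vector magnitude of the dynamic acceleration triplets,
#' `sqrt(dx^2 + dy^2 + dz^2)` - the locomotion proxy used throughout the
#' dead-reckoning pipeline.
#'
#' @param dynamic n x 3 matrix of dynamic acceleration (g), or a
#'   `badger_derived` object.
#' @return numeric vector (g), non-negative.
#' @export
compute_vedba <- function(dynamic) {
  if (inherits(dynamic, "badger_derived")) dynamic <- dynamic$dynamic
  sqrt(rowSums(dynamic^2))
}

#' Tilt-compensated compass heading
#'
#' Estimates pitch and roll from the static acceleration (body axes:
#' x forward, y left, z up; a level collar reads (0,0,1) g), de-rotates
#' the magnetometer triplets into the horizontal plane, and takes the
#' heading as the angle of the horizontal field clockwise from (magnetic)
#' north, in [0, 360). The result is invariant to uniform scaling of the
#' magnetometer units, so no field-intensity calibration is needed.
#'
#' Samples with zero static magnitude cannot be oriented; they are
#' flagged and their heading filled from the nearest valid neighbour.
#'
#' @param static n x 3 static acceleration (g), or a `badger_derived`.
#' @param mag n x 3 magnetometer triplets (ignored when `static` is a
#'   `badger_derived`, which carries its own).
#' @param calibration optional list(`A` = 3x3 matrix, `b` = offset 3-vector)
#'   applied to the raw magnetometer readings as `(mag - b) %*% t(A)`;
#'   hook for hard/soft-iron correction of real collar data.
#' @return A list of class `badger_heading`: `heading_deg` in [0, 360),
#'   `pitch_deg`, `roll_deg`, and logical `valid`.
#' @export
compute_heading <- function(static, mag = NULL, calibration = NULL) {
  if (inherits(static, "badger_derived")) {
    mag <- static$mag
    static <- static$static
  }
  if (!is.null(calibration)) {
    mag <- sweep(mag, 2, calibration$b) %*% t(calibration$A)
  }
  smag <- sqrt(rowSums(static^2))
  valid <- smag > 0
  sx <- static[, 1] / ifelse(valid, smag, 1)
  p <- asin(pmin(1, pmax(-1, sx)))
  r <- atan2(static[, 2], static[, 3])
  r[!valid] <- 0

  # de-tilt: Rx(roll) then Ry(-pitch) returns the field to the horizontal
  bx <- mag[, 1]
  by <- cos(r) * mag[, 2] - sin(r) * mag[, 3]
  bz <- sin(r) * mag[, 2] + cos(r) * mag[, 3]
  tx <- cos(p) * bx - sin(p) * bz
  ty <- by
  heading <- rad2deg(atan2(ty, tx)) %% 360
  if (!all(valid)) {
    if (!any(valid)) stop("no sample has non-zero static acceleration")
    heading[!valid] <- NA_real_
    first_ok <- which(valid)[1]
    heading[seq_len(first_ok - 1L)] <- heading[first_ok]
    heading <- locf(heading)
  }
  structure(
    list(heading_deg = heading,
         pitch_deg = rad2deg(p),
         roll_deg = rad2deg(r),
         valid = valid),
    class = "badger_heading"
  )
}

#' Derive VeDBA and heading from a raw sensor stream
#'
#' Convenience wrapper chaining [split_static_dynamic()], [compute_vedba()]
#' and [compute_heading()].
#' @inheritParams split_static_dynamic
#' @param calibration passed to [compute_heading()].
#' @return `badger_derived` with `vedba`, `heading_deg`, `pitch_deg`,
#'   `roll_deg` added.
#' @export
derive_signals <- function(stream, window_s = 2, calibration = NULL) {
  d <- split_static_dynamic(stream, window_s)
  d$vedba <- compute_vedba(d)
  hd <- compute_heading(d, calibration = calibration)
  d$heading_deg <- hd$heading_deg
  d$pitch_deg <- hd$pitch_deg
  d$roll_deg <- hd$roll_deg
  d
}

#' Detect sett occupancy from VeDBA and temperature
#'
#' A badger inside its sett shows strongly dampened VeDBA (from about
#' 0.25 g when active above ground to under 0.1 g) and, because the sett
#' is warmer than the night air, the collar temperature climbs by a few
#' degrees within about half an hour of entry. Detection is driven by the
#' VeDBA transition (the temperature sensor lags); a below-ground bout is
#' declared where the smoothed VeDBA stays below `theta_v` for at least
#' `min_bout_s`, and tagged with `evidence = "both"` when the temperature
#' also rises by at least `theta_t` within `temp_window_s` of entry.
#' Brief dips below the threshold (ordinary above-ground resting spells)
#' do not qualify as bouts, and brief pops above it during a long quiet
#' spell (shuffling inside the sett) are merged into the surrounding
#' below-ground bout, so the returned bouts tile the record with
#' alternating states and every bout lasts at least `min_bout_s`.
#'
#' @param vedba numeric VeDBA series (g) on a uniform grid.
#' @param temperature temperature series aligned with `vedba`, or NULL /
#'   all-NA for VeDBA-only detection.
#' @param fs sample rate (Hz).
#' @param time_s optional timestamps (defaults to 0-based grid).
#' @param theta_v VeDBA threshold (g), default 0.1.
#' @param min_bout_s minimum bout duration (s), default 300.
#' @param smooth_s VeDBA smoothing window (s), default 30: short enough
#'   that activity bursts and rests stay distinct, keeping the detected
#'   entry within about a minute of the true transition.
#' @param theta_t temperature-rise threshold (degC), default 3.
#' @param temp_window_s window after entry searched for the rise (s).
#' @return A data.frame of class `badger_bouts` with `start_s`, `end_s`,
#'   `state` (above_ground / below_ground) and `evidence` (vedba / both /
#'   none); the per-sample below-ground mask is kept as attribute
#'   `below_mask`.
#' @export
detect_sett_occupancy <- function(vedba, temperature = NULL, fs,
                                  time_s = NULL,
                                  theta_v = 0.1, min_bout_s = 300,
                                  smooth_s = 30, theta_t = 3,
                                  temp_window_s = 1800) {
  n <- length(vedba)
  if (is.null(time_s)) time_s <- (seq_len(n) - 1) / fs
  sm <- running_mean(vedba, as.integer(round(smooth_s * fs)))
  below <- sm < theta_v

  min_len <- as.integer(round(min_bout_s * fs))
  # a below-ground bout needs sustained quiet: sub-minimum quiet runs are
  # ordinary above-ground rests
  rl <- rle(below)
  rl$values[rl$values & rl$lengths < min_len] <- FALSE
  rl <- rle(inverse.rle(rl))
  # ... and brief active pops flanked by below-ground bouts belong to them
  if (length(rl$lengths) > 2L) {
    interior <- seq(2L, length(rl$lengths) - 1L)
    flip <- interior[!rl$values[interior] & rl$lengths[interior] < min_len]
    rl$values[flip] <- TRUE
    rl <- rle(inverse.rle(rl))
  }
  below <- inverse.rle(rl)

  ends <- cumsum(rl$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  have_temp <- !is.null(temperature) && any(!is.na(temperature))
  evidence <- character(length(starts))
  for (k in seq_along(starts)) {
    if (!rl$values[k]) {
      evidence[k] <- "none"
    } else if (!have_temp) {
      evidence[k] <- "vedba"
    } else {
      i0 <- starts[k]
      i1 <- min(n, i0 + as.integer(round(temp_window_s * fs)))
      tw <- temperature[i0:i1]
      rise <- suppressWarnings(max(tw, na.rm = TRUE)) - temperature[i0]
      evidence[k] <- if (is.finite(rise) && rise >= theta_t) "both" else "vedba"
    }
  }
  out <- data.frame(
    start_s = time_s[starts],
    end_s = time_s[ends] + 1 / fs,
    state = ifelse(rl$values, "below_ground", "above_ground"),
    evidence = evidence,
    stringsAsFactors = FALSE
  )
  structure(out,
            class = c("badger_bouts", "data.frame"),
            below_mask = below, fs = fs)
}
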