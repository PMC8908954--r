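#' Speed~VeDBA model
#'
#' Linear speed proxy `speed = max(0, m * VeDBA + c)`. The gradient `m`
#' is the quantity calibrated against GPS displacements; the intercept
#' defaults to 0.
#'
#' @param m gradient (m s^-1 per g), > 0.
#' @param c intercept (m s^-1), >= 0.
#' @return list of class `badger_speedmodel`.
#' @export
speed_model <- function(m, c = 0) {
  stopifnot(is.finite(m), m > 0, is.finite(c), c >= 0)
  structure(list(m = m, c = c), class = "badger_speedmodel")
}

#' @export
print.badger_speedmodel <- function(x, ...) {
  cat(sprintf("<badger_speedmodel> speed = max(0, %.4f * VeDBA + %.4f) m/s\n",
              x$m, x$c))
  if (!is.null(attr(x, "iterations"))) {
    cat(sprintf("  calibrated in %d iteration(s) over %d GPS segment(s)\n",
                attr(x, "iterations"), attr(x, "n_segments")))
  }
  invisible(x)
}

#' Construct a track object in the projected frame
#' @keywords internal
new_track <- function(time_s, easting, northing, source, epsg,
                      below = FALSE) {
  ll <- utm_unproject(easting, northing, epsg)
  below <- rep_len(below, length(time_s))
  structure(
    data.frame(time_s = time_s, easting = easting, northing = northing,
               lat = ll[, "lat"], lon = ll[, "lon"],
               below = below, stringsAsFactors = FALSE),
    class = c("badger_track", "data.frame"),
    source = source, epsg = epsg
  )
}

#' Source tag of a track (gps / dead_reckoned / truth)
#' @param track a `badger_track`
#' @export
track_source <- function(track) attr(track, "source")

#' Integrate a dead-reckoned path from VeDBA and heading
#'
#' Per sample: `speed_i = max(0, m * VeDBA_i + c)`; the displacement
#' `speed_i * dt` is laid along `heading_i` (clockwise from north, so
#' east = sin, north = cos) and cumulatively summed from `start` in the
#' projected plane. Samples flagged below ground contribute zero
#' displacement.
#'
#' @param vedba,heading_deg equal-length series.
#' @param model a [speed_model()].
#' @param start length-2 start position (easting, northing), m.
#' @param dt sample interval (s).
#' @param below optional logical mask of below-ground samples.
#' @return two-column matrix (easting, northing), one row per sample; the
#'   first row already includes the first sample's displacement.
#' @export
integrate_path <- function(vedba, heading_deg, model, start = c(0, 0),
                           dt, below = NULL) {
  if (length(vedba) != length(heading_deg)) {
    stop("vedba and heading series differ in length")
  }
  speed <- pmax(0, model$m * vedba + model$c)
  if (!is.null(below)) speed[below] <- 0
  h <- deg2rad(heading_deg)
  cbind(easting = start[1] + cumsum(speed * dt * sin(h)),
        northing = start[2] + cumsum(speed * dt * cos(h)))
}

#' Calibrate the speed~VeDBA gradient against GPS displacements
#'
#' First pass of the GPS-enabled scheme: integrate an uncalibrated track,
#' time-match the GPS fixes to dead-reckoned samples, then rescale the
#' gradient so the summed dead-reckoned displacement between consecutive
#' fixes agrees with the GPS-derived displacements in the least-squares
#' sense (one global gradient). The scale factor is re-estimated until
#' its relative change drops below `tol` (the zero-intercept model makes
#' each displacement linear in `m`, so this normally converges in one
#' update; the iteration guards the clamped/non-zero-intercept cases).
#'
#' @param vedba,heading_deg sensor-derived series on a uniform grid.
#' @param time_s sample timestamps (s).
#' @param fixes a `badger_gpsfixes` data.frame (or any with `time_s`,
#'   `lat`, `lon`).
#' @param initial starting [speed_model()].
#' @param fs sample rate (Hz).
#' @param below optional below-ground sample mask (those samples carry no
#'   displacement; GPS fixes inside below-ground intervals are dropped).
#' @param epsg projection for the GPS fixes.
#' @param tol,max_iter convergence control (relative change, default 1e-4,
#'   at most 50 iterations).
#' @return The fitted `badger_speedmodel`, with attributes `iterations`,
#'   `n_segments` and `segment_residual_m` (per-segment mismatch after
#'   fitting).
#' @export
calibrate_speed_model <- function(vedba, heading_deg, time_s, fixes,
                                  initial = speed_model(1), fs,
                                  below = NULL, epsg = 32629,
                                  tol = 1e-4, max_iter = 50) {
  en <- utm_project(fixes$lat, fixes$lon, epsg)
  keep <- fixes$time_s >= time_s[1] & fixes$time_s <= time_s[length(time_s)]
  idx <- round((fixes$time_s[keep] - time_s[1]) * fs) + 1L
  if (!is.null(below) && length(idx)) {
    ok <- !below[idx]
    idx <- idx[ok]
    en <- en[keep, , drop = FALSE][ok, , drop = FALSE]
  } else {
    en <- en[keep, , drop = FALSE]
  }
  if (length(idx) < 2) {
    attr(initial, "iterations") <- 0L
    attr(initial, "n_segments") <- 0L
    return(initial)
  }
  g_e <- diff(en[, "easting"])
  g_n <- diff(en[, "northing"])

  m <- initial$m
  iter <- 0L
  repeat {
    iter <- iter + 1L
    path <- integrate_path(vedba, heading_deg, speed_model(m, initial$c),
                           start = c(0, 0), dt = 1 / fs, below = below)
    d_e <- diff(path[idx, "easting"])
    d_n <- diff(path[idx, "northing"])
    denom <- sum(d_e^2 + d_n^2)
    if (denom == 0) {
      stop("calibration failure: VeDBA carries no speed signal over the GPS segments")
    }
    rho <- sum(d_e * g_e + d_n * g_n) / denom
    if (rho <= 0) {
      stop("calibration failure: dead-reckoned and GPS displacements are anti-correlated")
    }
    if (abs(rho - 1) < tol || iter >= max_iter) break
    m <- m * rho
  }
  fitted <- speed_model(m, initial$c)
  attr(fitted, "iterations") <- iter
  attr(fitted, "n_segments") <- length(g_e)
  attr(fitted, "segment_residual_m") <- sqrt((d_e - g_e)^2 + (d_n - g_n)^2)
  fitted
}

#' Anchor a dead-reckoned track to GPS fixes
#'
#' Current-style drift correction: the residual between each time-matched
#' GPS fix and the dead-reckoned position is interpolated linearly in
#' time across each inter-fix segment and added to the track, so the
#' corrected track passes through every usable fix while preserving the
#' dead-reckoned turn structure between them (before the first and after
#' the last fix the nearest residual is carried flat). Fixes outside the
#' track's time span are skipped with a warning.
#'
#' @param dr a `badger_track` (projected, uniform grid).
#' @param fixes GPS fixes with `time_s`, `lat`, `lon`.
#' @return Corrected `badger_track`; attribute `anchor_error_m` holds the
#'   per-fix distances after correction (all ~1e-9 m).
#' @export
gps_correct_track <- function(dr, fixes) {
  epsg <- attr(dr, "epsg")
  fs <- 1 / stats::median(diff(dr$time_s))
  inside <- fixes$time_s >= dr$time_s[1] & fixes$time_s <= dr$time_s[nrow(dr)]
  if (any(!inside)) {
    warning(sum(!inside), " GPS fix(es) outside the track time span skipped")
  }
  fx <- fixes[inside, , drop = FALSE]
  if (nrow(fx) == 0) return(dr)
  en <- utm_project(fx$lat, fx$lon, epsg)
  idx <- round((fx$time_s - dr$time_s[1]) * fs) + 1L
  res_e <- en[, "easting"] - dr$easting[idx]
  res_n <- en[, "northing"] - dr$northing[idx]
  if (nrow(fx) == 1) {
    corr_e <- rep(res_e, nrow(dr))
    corr_n <- rep(res_n, nrow(dr))
  } else {
    corr_e <- stats::approx(fx$time_s, res_e, xout = dr$time_s, rule = 2)$y
    corr_n <- stats::approx(fx$time_s, res_n, xout = dr$time_s, rule = 2)$y
  }
  out <- new_track(dr$time_s, dr$easting + corr_e, dr$northing + corr_n,
                   source = track_source(dr), epsg = epsg,
                   below = dr$below)
  attr(out, "anchor_error_m") <- sqrt(
    (en[, "easting"] - out$easting[idx])^2 +
      (en[, "northing"] - out$northing[idx])^2
  )
  out
}

#' GPS-enabled dead-reckoning of one night
#'
#' Orchestrates the full per-night reconstruction: derive VeDBA and
#' tilt-compensated heading from the raw stream, split the record into
#' above-ground bouts, and per bout calibrate the speed~VeDBA gradient,
#' integrate the path and anchor it to the GPS fixes. Below-ground
#' intervals are excluded from the output; per-bout tracks are
#' concatenated.
#'
#' @param stream a `badger_sensorstream`.
#' @param fixes a `badger_gpsfixes` data.frame (possibly empty).
#' @param bouts optional [detect_sett_occupancy()] result; computed from
#'   the stream (VeDBA + temperature) when NULL.
#' @param initial starting [speed_model()] (nominal gradient).
#' @param window_s static-filter window (s).
#' @param epsg projected CRS.
#' @return A `badger_track` with source `"dead_reckoned"` (or
#'   `"dead_reckoned_unanchored"` if no bout had any usable fix).
#'   Attributes: `models` (per-bout fitted speed models), `anchor_error_m`
#'   (pooled), `signals` (the derived VeDBA/heading, for reuse).
#' @export
dead_reckon <- function(stream, fixes, bouts = NULL,
                        initial = speed_model(1), window_s = 2,
                        epsg = stream$epsg %||% 32629) {
  sig <- derive_signals(stream, window_s)
  if (is.null(bouts)) {
    bouts <- detect_sett_occupancy(sig$vedba, stream$temp_c, fs = stream$fs,
                                   time_s = stream$time_s)
  }
  below <- attr(bouts, "below_mask")
  fs <- stream$fs
  above_bouts <- bouts[bouts$state == "above_ground", , drop = FALSE]
  pieces <- list()
  models <- list()
  anchor_err <- numeric(0)
  anchored_any <- FALSE
  for (b in seq_len(nrow(above_bouts))) {
    i0 <- round((above_bouts$start_s[b] - stream$time_s[1]) * fs) + 1L
    i1 <- round((above_bouts$end_s[b] - stream$time_s[1]) * fs)
    i1 <- min(i1, length(sig$vedba))
    seg <- i0:i1
    fseg <- fixes[fixes$time_s >= stream$time_s[i0] &
                  fixes$time_s <= stream$time_s[i1], , drop = FALSE]
    model <- initial
    if (nrow(fseg) >= 2) {
      model <- calibrate_speed_model(sig$vedba[seg], sig$heading_deg[seg],
                                     stream$time_s[seg], fseg,
                                     initial = initial, fs = fs, epsg = epsg)
    }
    path <- integrate_path(sig$vedba[seg], sig$heading_deg[seg], model,
                           start = c(0, 0), dt = 1 / fs)
    piece <- new_track(stream$time_s[seg], path[, "easting"],
                       path[, "northing"], source = "dead_reckoned",
                       epsg = epsg)
    anchored <- nrow(fseg) >= 1
    if (anchored) {
      piece <- gps_correct_track(piece, fseg)
      anchor_err <- c(anchor_err, attr(piece, "anchor_error_m"))
      anchored_any <- TRUE
    }
    attr(piece, "anchored") <- anchored
    models[[length(models) + 1L]] <- model
    pieces[[length(pieces) + 1L]] <- piece
  }
  # chain bouts without any fix onto their anchored neighbours so the
  # night-level track is spatially continuous: an unanchored bout starts
  # where the previous bout ended (or, for a leading bout, ends where the
  # following anchored bout starts)
  if (length(pieces) > 1) {
    for (b in seq_along(pieces)) {
      if (isTRUE(attr(pieces[[b]], "anchored"))) next
      if (b > 1) {
        prev <- pieces[[b - 1]]
        shift <- c(prev$easting[nrow(prev)] - pieces[[b]]$easting[1],
                   prev$northing[nrow(prev)] - pieces[[b]]$northing[1])
      } else {
        nxt <- pieces[[b + 1]]
        np <- nrow(pieces[[b]])
        shift <- c(nxt$easting[1] - pieces[[b]]$easting[np],
                   nxt$northing[1] - pieces[[b]]$northing[np])
      }
      shifted <- new_track(pieces[[b]]$time_s,
                           pieces[[b]]$easting + shift[1],
                           pieces[[b]]$northing + shift[2],
                           source = "dead_reckoned", epsg = epsg)
      attr(shifted, "anchored") <- FALSE
      pieces[[b]] <- shifted
    }
  }
  if (length(pieces) == 0) {
    out <- new_track(numeric(0), numeric(0), numeric(0),
                     source = "dead_reckoned", epsg = epsg)
  } else {
    df <- do.call(rbind, lapply(pieces, as.data.frame))
    out <- structure(df, class = c("badger_track", "data.frame"),
                     source = if (anchored_any) "dead_reckoned"
                              else "dead_reckoned_unanchored",
                     epsg = epsg)
  }
  attr(out, "models") <- models
  attr(out, "anchor_error_m") <- anchor_err
  attr(out, "signals") <- sig
  attr(out, "bouts") <- bouts
  out
}

#' GPS-only track from fixes
#'
#' @param fixes a `badger_gpsfixes` data.frame.
#' @param epsg projected CRS.
#' @return `badger_track` with source `"gps"`.
#' @export
gps_track <- function(fixes, epsg = attr(fixes, "epsg") %||% 32629) {
  en <- utm_project(fixes$lat, fixes$lon, epsg)
  new_track(fixes$time_s, en[, "easting"], en[, "northing"],
            source = "gps", epsg = epsg)
}

#' Straight-line GPS interpolation at arbitrary times
#'
#' The track a GPS-only analysis implies: linear interpolation between
#' consecutive fixes in the projected plane, defined only inside the fix
#' time span.
#' @param fixes GPS fixes.
#' @param time_s times at which to interpolate.
#' @param epsg projected CRS.
#' @return two-column matrix (easting, northing) with NA outside the span.
#' @export
gps_interpolate <- function(fixes, time_s, epsg = attr(fixes, "epsg") %||% 32629) {
  en <- utm_project(fixes$lat, fixes$lon, epsg)
  if (nrow(fixes) < 2) {
    return(cbind(easting = rep(NA_real_, length(time_s)),
                 northing = NA_real_))
  }
  cbind(
    easting = stats::approx(fixes$time_s, en[, "easting"], xout = time_s)$y,
    northing = stats::approx(fixes$time_s, en[, "northing"], xout = time_s)$y
  )
}

#' RMS position error of a track against the ground truth
#'
#' Matches samples by timestamp (uniform truth grid) and returns the root
#' mean square planar distance.
#' @param track a `badger_track` or a matrix of positions with times.
#' @param truth a `badger_truetrack`.
#' @param time_s timestamps of `track` rows (taken from the track when
#'   omitted).
#' @return RMS error in metres.
#' @export
track_rmse <- function(track, truth, time_s = NULL) {
  if (is.null(time_s)) time_s <- track$time_s
  fs <- attr(truth, "fs")
  idx <- round((time_s - truth$time_s[1]) * fs) + 1L
  ok <- idx >= 1L & idx <= nrow(truth)
  e <- if (is.data.frame(track)) track$easting else track[, "easting"]
  nn <- if (is.data.frame(track)) track$northing else track[, "northing"]
  ok <- ok & !is.na(e)
  sqrt(mean((e[ok] - truth$easting[idx[ok]])^2 +
              (nn[ok] - truth$northing[idx[ok]])^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
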