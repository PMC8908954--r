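# Delimited-text interchange for sensor streams, GPS fixes and ground
# truth. All files are plain text so synthetic study bundles can be
# regenerated and inspected anywhere.

#' Write a sensor stream as CSV
#'
#' Columns: time_s, ax_g, ay_g, az_g, mx, my, mz, temp_c, temp_valid.
#' Temperature is the 7 Hz channel held on the 40 Hz grid; `temp_valid`
#' marks the samples at which a fresh native reading was taken.
#'
#' @param stream a `badger_sensorstream`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(stream, path) {
  dt <- data.table::data.table(
    time_s = stream$time_s,
    ax_g = stream$acc[, 1], ay_g = stream$acc[, 2], az_g = stream$acc[, 3],
    mx = stream$mag[, 1], my = stream$mag[, 2], mz = stream$mag[, 3],
    temp_c = stream$temp_c,
    temp_valid = as.integer(stream$temp_valid)
  )
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a sensor stream CSV written by [write_sensor_csv()]
#'
#' @param path file path.
#' @param fs,temp_fs sample rates (Hz); `fs` defaults to the inverse
#'   median time step of the file.
#' @return a `badger_sensorstream`.
#' @export
read_sensor_csv <- function(path, fs = NULL, temp_fs = 7) {
  dt <- data.table::fread(path)
  if (is.null(fs)) fs <- round(1 / stats::median(diff(dt$time_s)))
  structure(
    list(time_s = dt$time_s,
         acc = as.matrix(dt[, c("ax_g", "ay_g", "az_g")]),
         mag = as.matrix(dt[, c("mx", "my", "mz")]),
         temp_c = dt$temp_c,
         temp_valid = as.logical(dt$temp_valid),
         fs = fs, temp_fs = temp_fs),
    class = "badger_sensorstream"
  )
}

#' Write GPS fixes as CSV (time_iso8601, lat, lon)
#' @param fixes a `badger_gpsfixes` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gps_csv <- function(fixes, path) {
  data.table::fwrite(data.table::data.table(
    time_iso8601 = fixes$time_iso,
    time_s = fixes$time_s,
    lat = fixes$lat, lon = fixes$lon,
    error_m = fixes$error_m
  ), path)
  invisible(path)
}

#' Read GPS fixes from CSV
#' @param path file path.
#' @return data.frame of class `badger_gpsfixes`.
#' @export
read_gps_csv <- function(path) {
  dt <- as.data.frame(data.table::fread(path))
  out <- data.frame(time_s = dt$time_s,
                    time_iso = dt$time_iso8601,
                    lat = dt$lat, lon = dt$lon,
                    error_m = if ("error_m" %in% names(dt)) dt$error_m else NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("badger_gpsfixes", "data.frame")
  out
}

#' Write GPS fixes as GPX 1.1
#'
#' One track with one segment; fix times go into `<time>` elements.
#' @param fixes a `badger_gpsfixes` data.frame.
#' @param path output path.
#' @param name track name.
#' @return `path`, invisibly.
#' @export
write_gpx <- function(fixes, path, name = "badger") {
  doc <- xml2::xml_new_root("gpx",
                            version = "1.1", creator = "badgerdr",
                            xmlns = "http://www.topografix.com/GPX/1/1")
  trk <- xml2::xml_add_child(doc, "trk")
  xml2::xml_add_child(trk, "name", name)
  seg <- xml2::xml_add_child(trk, "trkseg")
  for (i in seq_len(nrow(fixes))) {
    pt <- xml2::xml_add_child(seg, "trkpt",
                              lat = sprintf("%.8f", fixes$lat[i]),
                              lon = sprintf("%.8f", fixes$lon[i]))
    xml2::xml_add_child(pt, "time", fixes$time_iso[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read GPS fixes from a GPX 1.1 file
#' @param path file path.
#' @return data.frame of class `badger_gpsfixes` (`time_s` reconstructed
#'   as seconds from midnight UTC of the first point's date).
#' @export
read_gpx <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  pts <- xml2::xml_find_all(doc, ".//g:trkpt", ns)
  lat <- as.numeric(xml2::xml_attr(pts, "lat"))
  lon <- as.numeric(xml2::xml_attr(pts, "lon"))
  iso <- xml2::xml_text(xml2::xml_find_first(pts, "./g:time", ns))
  tt <- as.POSIXct(iso, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  day0 <- as.POSIXct(format(tt[1], "%Y-%m-%d"), tz = "UTC")
  out <- data.frame(time_s = as.numeric(difftime(tt, day0, units = "secs")),
                    time_iso = iso, lat = lat, lon = lon,
                    error_m = NA_real_, stringsAsFactors = FALSE)
  class(out) <- c("badger_gpsfixes", "data.frame")
  out
}

#' Write the ground-truth sidecar bundle for one night
#'
#' Truth positions (thinned to 1 Hz to keep files light), the full
#' occupancy mask at 1 Hz, and the generating parameters as JSON.
#' Intended for accuracy assessment and tests, not for analysis input.
#'
#' @param truth a `badger_truetrack`.
#' @param path_csv,path_json output paths.
#' @return invisibly, the two paths.
#' @export
write_truth_bundle <- function(truth, path_csv, path_json) {
  fs <- attr(truth, "fs")
  idx <- seq(1, nrow(truth), by = fs)
  data.table::fwrite(data.table::data.table(
    time_s = truth$time_s[idx],
    easting = truth$easting[idx],
    northing = truth$northing[idx],
    speed_ms = truth$speed_ms[idx],
    state = truth$state[idx],
    above = as.integer(truth$above[idx])
  ), path_csv)
  pars <- list(animal = attr(truth, "animal"), night = attr(truth, "night"),
               fs = fs, epsg = attr(truth, "epsg"),
               m_true = attr(truth, "m_true"), c_true = attr(truth, "c_true"),
               emergence_s = attr(truth, "emergence_s"),
               return_s = attr(truth, "return_s"),
               true_path_km = true_path_length_km(truth))
  writeLines(jsonlite::toJSON(pars, auto_unbox = TRUE, digits = NA),
             path_json)
  invisible(c(path_csv, path_json))
}
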