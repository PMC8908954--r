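#' Study configuration: simulation plus analysis parameters
#'
#' Wraps a [sim_config()] together with every tunable analysis-stage
#' parameter (static-filter window, sett-detection thresholds, proximity
#' radius, home-range level/trim/bandwidth rule, nominal starting
#' gradient) so a whole run is reproducible from one object.
#'
#' @param seed root seed (propagated into `sim` unless one is supplied).
#' @param sim a [sim_config()].
#' @param window_s static-acceleration smoothing window (s).
#' @param theta_v,min_bout_s,smooth_s,theta_t,temp_window_s sett-occupancy
#'   detection parameters, see [detect_sett_occupancy()].
#' @param radius_m habitat proximity radius (m).
#' @param hr_level home-range inclusion level (0.95 -> MCP95/KD95).
#' @param hr_trim outlier fraction trimmed before home ranges.
#' @param kde_grid_n KDE grid resolution per axis.
#' @param kde_bandwidth fixed KDE bandwidth (m) or NULL for the
#'   reference rule.
#' @param initial_m nominal speed~VeDBA gradient starting the calibration.
#' @return list of class `badger_studyconfig`.
#' @export
study_config <- function(seed = 1L, sim = sim_config(seed = seed),
                         window_s = 2,
                         theta_v = 0.1, min_bout_s = 300, smooth_s = 30,
                         theta_t = 3, temp_window_s = 1800,
                         radius_m = 20,
                         hr_level = 0.95, hr_trim = 0.05,
                         kde_grid_n = 200, kde_bandwidth = NULL,
                         initial_m = 1.0) {
  cfg <- as.list(environment())
  class(cfg) <- "badger_studyconfig"
  cfg
}

#' Simulate one badger-night (truth, sensors, GPS)
#'
#' @param config a `badger_studyconfig` or `badger_simconfig`.
#' @param animal,night indices.
#' @param landscape optional pre-built landscape.
#' @return list with `truth`, `stream`, `fixes`.
#' @export
simulate_night <- function(config, animal = 1L, night = 1L,
                           landscape = NULL) {
  sim <- if (inherits(config, "badger_studyconfig")) config$sim else config
  if (is.null(landscape)) landscape <- generate_landscape(sim)
  truth <- simulate_true_track(sim, animal, night, landscape)
  stream <- render_sensor_streams(truth, sim)
  fixes <- sample_gps(truth, sim)
  list(truth = truth, stream = stream, fixes = fixes)
}

#' Analyse one badger-night
#'
#' Runs the sensor-processing and dead-reckoning stages for a single
#' night and, when a landscape is supplied, the habitat-proximity
#' budgets for both the dead-reckoned and the GPS track.
#'
#' @param stream a `badger_sensorstream`.
#' @param fixes GPS fixes for the night.
#' @param sc a [study_config()].
#' @param landscape optional `badger_landscape`.
#' @param truth optional ground truth for accuracy metrics.
#' @return list with `bouts`, `dr` and `gps` tracks, `metrics` (one-row
#'   data.frame), and proximity budgets (`prox_dr`, `prox_gps`).
#' @export
analyse_night <- function(stream, fixes, sc = study_config(),
                          landscape = NULL, truth = NULL) {
  sig <- derive_signals(stream, sc$window_s)
  bouts <- detect_sett_occupancy(sig$vedba, stream$temp_c, fs = stream$fs,
                                 time_s = stream$time_s,
                                 theta_v = sc$theta_v,
                                 min_bout_s = sc$min_bout_s,
                                 smooth_s = sc$smooth_s,
                                 theta_t = sc$theta_t,
                                 temp_window_s = sc$temp_window_s)
  dr <- dead_reckon(stream, fixes, bouts = bouts,
                    initial = speed_model(sc$initial_m),
                    window_s = sc$window_s,
                    epsg = stream$epsg %||% sc$sim$epsg)
  gps <- gps_track(fixes, epsg = stream$epsg %||% sc$sim$epsg)

  models <- attr(dr, "models")
  fitted <- vapply(models, function(m) {
    if (!is.null(attr(m, "n_segments")) && attr(m, "n_segments") >= 1) m$m
    else NA_real_
  }, numeric(1))
  above <- bouts[bouts$state == "above_ground", , drop = FALSE]

  metrics <- data.frame(
    animal = stream$animal %||% NA_integer_,
    night = stream$night %||% NA_integer_,
    n_fixes = nrow(fixes),
    above_h = sum(above$end_s - above$start_s) / 3600,
    path_km_dr = path_length_km(dr),
    path_km_gps = path_length_km(gps),
    m_fitted = if (all(is.na(fitted))) NA_real_ else
      mean(fitted, na.rm = TRUE),
    anchor_max_m = if (length(attr(dr, "anchor_error_m"))) {
      max(attr(dr, "anchor_error_m"))
    } else NA_real_
  )
  if (!is.null(truth)) {
    span <- range(fixes$time_s)
    in_span <- dr$time_s >= span[1] & dr$time_s <= span[2]
    metrics$dr_rmse_m <- track_rmse(dr[in_span, , drop = FALSE], truth)
    gi <- gps_interpolate(fixes, dr$time_s[in_span])
    metrics$gps_interp_rmse_m <- track_rmse(gi, truth,
                                            time_s = dr$time_s[in_span])
    metrics$sett_agreement <-
      mean(attr(bouts, "below_mask") == !truth$above)
    metrics$true_path_km <- true_path_length_km(truth)
  }
  out <- list(bouts = bouts, dr = dr, gps = gps, metrics = metrics)
  if (!is.null(landscape)) {
    out$prox_dr <- proximity_times(dr, landscape, sc$radius_m,
                                   fs = stream$fs)
    out$prox_gps <- proximity_times(gps, landscape, sc$radius_m)
  }
  out
}

#' Run the full synthetic study in memory
#'
#' Simulates and analyses every animal-night of the configured study
#' (default: two badgers over seven nights), then assembles the study-
#' level products: the per-night metric table, MCP95/KD95 home ranges
#' per animal and source, habitat-proximity proportions, and the
#' statistical comparisons (paired t GPS vs dead-reckoned; Welch t
#' between animals; one-way land-use models with Tukey HSD).
#'
#' @param config a [study_config()].
#' @param quiet suppress per-night progress messages.
#' @return list of class `badger_study`: `night_metrics`, `proximity`
#'   (long table), `home_ranges`, `tests`, `landuse`, `landscape`,
#'   `config`.
#' @export
run_study <- function(config = study_config(), quiet = TRUE) {
  sim <- config$sim
  landscape <- generate_landscape(sim)
  classes <- landscape_classes(landscape)

  metric_rows <- list()
  prox_rows <- list()
  pts <- list()  # per animal/source pooled projected points

  for (a in seq_len(sim$n_animals)) {
    for (ni in seq_len(sim$n_nights)) {
      if (!quiet) message(sprintf("animal %d night %d ...", a, ni))
      nt <- simulate_night(config, a, ni, landscape)
      an <- analyse_night(nt$stream, nt$fixes, config, landscape,
                          truth = nt$truth)
      metric_rows[[length(metric_rows) + 1L]] <- an$metrics
      for (src in c("dr", "gps")) {
        pr <- an[[paste0("prox_", src)]]
        pr$animal <- a
        pr$night <- ni
        pr$source <- src
        prox_rows[[length(prox_rows) + 1L]] <- as.data.frame(pr)
        key <- paste(a, src)
        tr <- if (src == "dr") an$dr else an$gps
        pts[[key]] <- rbind(pts[[key]], cbind(tr$easting, tr$northing))
      }
    }
  }
  night_metrics <- do.call(rbind, metric_rows)
  proximity <- do.call(rbind, prox_rows)

  hr_rows <- list()
  home_ranges <- list()
  for (a in seq_len(sim$n_animals)) {
    for (src in c("gps", "dr")) {
      p <- pts[[paste(a, src)]]
      mcp <- mcp_area(p, level = config$hr_level, source = src)
      kde <- kde_home_range(p, level = config$hr_level,
                            bandwidth = config$kde_bandwidth,
                            grid_n = config$kde_grid_n,
                            trim = config$hr_trim, source = src)
      home_ranges[[paste(a, src, "mcp")]] <- mcp
      home_ranges[[paste(a, src, "kde")]] <- kde
      hr_rows[[length(hr_rows) + 1L]] <- data.frame(
        animal = a, source = src,
        method = c(mcp$method, kde$method),
        area_km2 = c(mcp$area_km2, kde$area_km2),
        bandwidth_m = c(NA_real_, kde$bandwidth_m)
      )
    }
  }
  hr_table <- do.call(rbind, hr_rows)

  # --- statistical comparisons --------------------------------------
  tests <- list(
    path_paired = paired_comparison(night_metrics$path_km_dr,
                                    night_metrics$path_km_gps)
  )
  if (sim$n_animals >= 2) {
    a1 <- night_metrics$animal == 1
    tests$path_welch_gps <- welch_comparison(night_metrics$path_km_gps[a1],
                                             night_metrics$path_km_gps[!a1])
    tests$path_welch_dr <- welch_comparison(night_metrics$path_km_dr[a1],
                                            night_metrics$path_km_dr[!a1])
  }
  for (cl in classes) {
    d <- proximity[proximity$class == cl, ]
    wide <- merge(d[d$source == "dr", c("animal", "night", "proportion")],
                  d[d$source == "gps", c("animal", "night", "proportion")],
                  by = c("animal", "night"), suffixes = c("_dr", "_gps"))
    tests[[paste0("prox_paired_", cl)]] <-
      paired_comparison(wide$proportion_dr, wide$proportion_gps)
  }

  landuse <- list()
  for (src in c("gps", "dr")) {
    d <- proximity[proximity$source == src, ]
    val <- d$proportion
    transform_cl <- d$class %in% c("building", "road")
    val[transform_cl] <- log10_plus_one(val[transform_cl])
    landuse[[src]] <- landuse_model(data.frame(value = val, class = d$class))
  }

  structure(
    list(night_metrics = night_metrics,
         proximity = proximity,
         home_ranges = hr_table,
         home_range_objects = home_ranges,
         tests = tests,
         landuse = landuse,
         landscape = landscape,
         config = config),
    class = "badger_study"
  )
}

#' @export
print.badger_study <- function(x, ...) {
  nm <- x$night_metrics
  cat(sprintf("<badger_study> %d badger-night(s)\n", nrow(nm)))
  cat(sprintf("  path length (km): DR %.2f +/- %.2f, GPS %.2f +/- %.2f (ratio %.2f)\n",
              mean(nm$path_km_dr), stats::sd(nm$path_km_dr),
              mean(nm$path_km_gps), stats::sd(nm$path_km_gps),
              mean(nm$path_km_dr) / mean(nm$path_km_gps)))
  hr <- x$home_ranges
  for (m in unique(hr$method)) {
    h <- hr[hr$method == m, ]
    cat(sprintf("  %s (km^2): DR %.3f, GPS %.3f\n", m,
                mean(h$area_km2[h$source == "dr"]),
                mean(h$area_km2[h$source == "gps"])))
  }
  invisible(x)
}

#' Write a full synthetic study bundle to disk
#'
#' Per animal-night: sensor CSV, GPS CSV + GPX, truth sidecar (1 Hz CSV +
#' parameter JSON); plus the landscape GeoJSON and a manifest with MD5
#' checksums and a hash of the generating parameters.
#'
#' @param config a [study_config()].
#' @param out_dir output directory (created if missing).
#' @param quiet suppress progress messages.
#' @return path of the manifest file, invisibly.
#' @export
run_simulate <- function(config = study_config(), out_dir, quiet = TRUE) {
  sim <- config$sim
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    if (!quiet) message("created output directory ", out_dir)
  }
  landscape <- generate_landscape(sim)
  write_landscape_geojson(landscape, file.path(out_dir, "landscape.geojson"))
  files <- "landscape.geojson"
  for (a in seq_len(sim$n_animals)) {
    for (ni in seq_len(sim$n_nights)) {
      if (!quiet) message(sprintf("simulating animal %d night %d ...", a, ni))
      nt <- simulate_night(config, a, ni, landscape)
      stem <- sprintf("animal%d_night%d", a, ni)
      write_sensor_csv(nt$stream, file.path(out_dir, paste0(stem, "_sensors.csv")))
      write_gps_csv(nt$fixes, file.path(out_dir, paste0(stem, "_gps.csv")))
      write_gpx(nt$fixes, file.path(out_dir, paste0(stem, "_gps.gpx")),
                name = stem)
      write_truth_bundle(nt$truth,
                         file.path(out_dir, paste0(stem, "_truth.csv")),
                         file.path(out_dir, paste0(stem, "_truth.json")))
      files <- c(files, paste0(stem, c("_sensors.csv", "_gps.csv",
                                       "_gps.gpx", "_truth.csv",
                                       "_truth.json")))
    }
  }
  par_file <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(config$sim[setdiff(names(config$sim), "base_date")],
                              auto_unbox = TRUE, digits = NA), par_file)
  manifest <- list(
    n_animals = sim$n_animals,
    n_nights = sim$n_nights,
    seed = sim$seed,
    epsg = sim$epsg,
    parameter_hash = unname(tools::md5sum(par_file)),
    files = lapply(files, function(f) {
      list(name = f, md5 = unname(tools::md5sum(file.path(out_dir, f))))
    })
  )
  unlink(par_file)
  mf <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE), mf)
  invisible(mf)
}

#' Analyse a study bundle from disk
#'
#' File-based counterpart of [run_study()]: reads the bundle written by
#' [run_simulate()] (sensor CSVs, GPS CSVs, landscape GeoJSON, optional
#' truth sidecars), runs the full analysis and writes the result tables
#' (night metrics, home ranges, proximity budgets, test results), the
#' home-range polygons as GeoJSON, 1 Hz-thinned track GeoJSONs, and a
#' plain-text summary. With `gps_only = TRUE` (or when sensor files are
#' absent) the dead-reckoning side is skipped with a warning.
#'
#' @param in_dir directory holding a [run_simulate()] bundle.
#' @param out_dir output directory (created if missing).
#' @param sc a [study_config()] providing the analysis parameters.
#' @param gps_only analyse only the GPS side.
#' @param quiet suppress progress messages.
#' @return the summary list, invisibly (same shape as [run_study()] for
#'   the components that apply, plus `accuracy` when truth was present).
#' @export
run_analyse <- function(in_dir, out_dir, sc = study_config(),
                        gps_only = FALSE, quiet = TRUE) {
  mf_path <- file.path(in_dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", in_dir)
  manifest <- jsonlite::fromJSON(mf_path, simplifyVector = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  landscape <- read_landscape_geojson(file.path(in_dir, "landscape.geojson"))

  metric_rows <- list()
  prox_rows <- list()
  pts <- list()
  acc_rows <- list()
  for (a in seq_len(manifest$n_animals)) {
    for (ni in seq_len(manifest$n_nights)) {
      stem <- sprintf("animal%d_night%d", a, ni)
      gps_f <- file.path(in_dir, paste0(stem, "_gps.csv"))
      sen_f <- file.path(in_dir, paste0(stem, "_sensors.csv"))
      if (!file.exists(gps_f)) {
        stop("missing GPS file for ", stem, ": ", gps_f)
      }
      fixes <- read_gps_csv(gps_f)
      do_dr <- !gps_only && file.exists(sen_f)
      if (!do_dr && !gps_only) {
        warning("no sensor stream for ", stem,
                "; dead-reckoning skipped for this night")
      }
      if (!quiet) message("analysing ", stem, " ...")
      if (do_dr) {
        stream <- read_sensor_csv(sen_f, temp_fs = sc$sim$temp_fs)
        stream$epsg <- manifest$epsg
        stream$animal <- a
        stream$night <- ni
        an <- analyse_night(stream, fixes, sc, landscape)
        metric_rows[[length(metric_rows) + 1L]] <- an$metrics
        for (src in c("dr", "gps")) {
          pr <- an[[paste0("prox_", src)]]
          pr$animal <- a; pr$night <- ni; pr$source <- src
          prox_rows[[length(prox_rows) + 1L]] <- as.data.frame(pr)
          tr <- if (src == "dr") an$dr else an$gps
          pts[[paste(a, src)]] <- rbind(pts[[paste(a, src)]],
                                        cbind(tr$easting, tr$northing))
        }
        thin <- an$dr[seq(1, nrow(an$dr), by = round(stream$fs)), ]
        write_track_geojson(thin, manifest$epsg,
                            file.path(out_dir, paste0(stem, "_dr_track.geojson")))
        truth_f <- file.path(in_dir, paste0(stem, "_truth.csv"))
        if (file.exists(truth_f)) {
          acc_rows[[length(acc_rows) + 1L]] <-
            .accuracy_row(a, ni, an$dr, fixes, truth_f)
        }
      } else {
        g <- gps_track(fixes, epsg = manifest$epsg)
        pr <- proximity_times(g, landscape, sc$radius_m)
        pr$animal <- a; pr$night <- ni; pr$source <- "gps"
        prox_rows[[length(prox_rows) + 1L]] <- as.data.frame(pr)
        pts[[paste(a, "gps")]] <- rbind(pts[[paste(a, "gps")]],
                                        cbind(g$easting, g$northing))
        metric_rows[[length(metric_rows) + 1L]] <- data.frame(
          animal = a, night = ni, n_fixes = nrow(fixes),
          above_h = NA_real_, path_km_dr = NA_real_,
          path_km_gps = path_length_km(g), m_fitted = NA_real_,
          anchor_max_m = NA_real_)
      }
    }
  }

  night_metrics <- do.call(rbind, metric_rows)
  proximity <- do.call(rbind, prox_rows)
  sources <- if (gps_only || is.null(pts[["1 dr"]])) "gps" else c("gps", "dr")
  hr_rows <- list()
  for (a in seq_len(manifest$n_animals)) {
    for (src in sources) {
      p <- pts[[paste(a, src)]]
      if (is.null(p)) next
      mcp <- mcp_area(p, level = sc$hr_level, source = src)
      kde <- kde_home_range(p, level = sc$hr_level,
                            bandwidth = sc$kde_bandwidth,
                            grid_n = sc$kde_grid_n, trim = sc$hr_trim,
                            source = src)
      write_homerange_geojson(list(mcp, kde), manifest$epsg,
        file.path(out_dir, sprintf("animal%d_%s_homeranges.geojson", a, src)))
      hr_rows[[length(hr_rows) + 1L]] <- data.frame(
        animal = a, source = src, method = c(mcp$method, kde$method),
        area_km2 = c(mcp$area_km2, kde$area_km2),
        bandwidth_m = c(NA_real_, kde$bandwidth_m))
    }
  }
  hr_table <- do.call(rbind, hr_rows)

  res <- list(night_metrics = night_metrics, proximity = proximity,
              home_ranges = hr_table, config = sc)
  if ("dr" %in% sources) {
    res$tests <- list(path_paired = paired_comparison(
      night_metrics$path_km_dr, night_metrics$path_km_gps))
  }
  if (length(acc_rows)) res$accuracy <- do.call(rbind, acc_rows)

  data.table::fwrite(night_metrics, file.path(out_dir, "night_metrics.csv"))
  data.table::fwrite(proximity, file.path(out_dir, "proximity.csv"))
  data.table::fwrite(hr_table, file.path(out_dir, "home_ranges.csv"))
  if (!is.null(res$accuracy)) {
    data.table::fwrite(res$accuracy, file.path(out_dir, "accuracy.csv"))
  }
  writeLines(.study_summary_text(res), file.path(out_dir, "summary.txt"))
  invisible(res)
}

.accuracy_row <- function(a, ni, dr, fixes, truth_f) {
  tr <- as.data.frame(data.table::fread(truth_f))
  span <- range(fixes$time_s)
  sel <- dr$time_s >= span[1] & dr$time_s <= span[2]
  idx <- findInterval(dr$time_s[sel], tr$time_s)
  ok <- idx >= 1
  dr_rmse <- sqrt(mean((dr$easting[sel][ok] - tr$easting[idx[ok]])^2 +
                         (dr$northing[sel][ok] - tr$northing[idx[ok]])^2))
  gi <- gps_interpolate(fixes, tr$time_s, epsg = attr(dr, "epsg"))
  gok <- !is.na(gi[, 1])
  gps_rmse <- sqrt(mean((gi[gok, 1] - tr$easting[gok])^2 +
                          (gi[gok, 2] - tr$northing[gok])^2))
  data.frame(animal = a, night = ni,
             dr_rmse_m = dr_rmse, gps_interp_rmse_m = gps_rmse)
}

.study_summary_text <- function(res) {
  nm <- res$night_metrics
  lines <- c("Synthetic badger study: GPS vs GPS-enabled dead-reckoning",
             sprintf("badger-nights analysed: %d", nrow(nm)))
  if (any(!is.na(nm$path_km_dr))) {
    lines <- c(lines, sprintf(
      "path length km: DR %.2f +/- %.2f vs GPS %.2f +/- %.2f (ratio %.2f)",
      mean(nm$path_km_dr, na.rm = TRUE), stats::sd(nm$path_km_dr, na.rm = TRUE),
      mean(nm$path_km_gps), stats::sd(nm$path_km_gps),
      mean(nm$path_km_dr, na.rm = TRUE) / mean(nm$path_km_gps)))
  }
  hr <- res$home_ranges
  for (m in unique(hr$method)) {
    for (src in unique(hr$source)) {
      h <- hr[hr$method == m & hr$source == src, ]
      if (nrow(h)) {
        lines <- c(lines, sprintf("%s %s km^2: %s", m, src,
                                  paste(sprintf("%.4f", h$area_km2),
                                        collapse = ", ")))
      }
    }
  }
  lines
}

#' Write a track as GeoJSON LineString (WGS84)
#' @param track a `badger_track`.
#' @param epsg projected CRS recorded in properties.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track_geojson <- function(track, epsg, path) {
  coords <- lapply(seq_len(nrow(track)), function(i) {
    c(round(track$lon[i], 8), round(track$lat[i], 8))
  })
  gj <- list(type = "FeatureCollection",
             properties = list(projected_epsg = epsg,
                               source = track_source(track)),
             features = list(list(
               type = "Feature",
               properties = list(source = track_source(track)),
               geometry = list(type = "LineString", coordinates = coords))))
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = 8), path)
  invisible(path)
}

#' Write home-range polygon sets as GeoJSON (WGS84)
#' @param ranges list of `badger_homerange` objects.
#' @param epsg projected CRS of the polygon rings.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_homerange_geojson <- function(ranges, epsg, path) {
  feats <- lapply(ranges, function(hr) {
    polys <- lapply(hr$polygons, function(ring) {
      ring <- close_ring(ring)
      ll <- utm_unproject(ring[, 1], ring[, 2], epsg)
      list(lapply(seq_len(nrow(ll)), function(i) {
        c(round(ll[i, "lon"], 8), round(ll[i, "lat"], 8))
      }))
    })
    list(type = "Feature",
         properties = list(method = hr$method, source = hr$source,
                           area_km2 = hr$area_km2,
                           projected_epsg = epsg),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  gj <- list(type = "FeatureCollection",
             properties = list(projected_epsg = epsg),
             features = feats)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = 8), path)
  invisible(path)
}
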