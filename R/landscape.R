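#' Generate the synthetic farmland landscape
#'
#' Builds a deterministic fields-with-hedgerows landscape in the projected
#' frame: a grid of square fields separated by hedge strips along internal
#' boundaries, plus one building and one road placed just outside the
#' field block. The four feature classes (field, hedge, building, road)
#' are the ones whose 20 m proximity budgets the analysis reports.
#'
#' The landscape centre (the main sett) sits at the projected position of
#' `config$origin_lat/lon`. Output is deterministic for a given config.
#'
#' @param config a [sim_config()].
#' @return An object of class `badger_landscape`: list with `polygons`
#'   (each `list(class=, ring=)` in projected metres), `bbox`
#'   (xmin/ymin/xmax/ymax used to confine simulated tracks), `sett`
#'   (projected coordinates) and `epsg`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "badger_simconfig"))
  nx <- as.integer(config$field_grid[1])
  ny <- as.integer(config$field_grid[2])
  if (nx < 1 || ny < 1) stop("field grid dimensions must be >= 1x1")
  s <- config$field_size_m
  w <- config$hedge_width_m
  if (w <= 0) {
    warning("hedge width <= 0; rendering hedges as 1 m minimal strips")
    w <- 1
  }

  sett <- utm_project(config$origin_lat, config$origin_lon, config$epsg)[1, ]
  x0 <- sett[["easting"]] - nx * s / 2
  y0 <- sett[["northing"]] - ny * s / 2
  x1 <- x0 + nx * s
  y1 <- y0 + ny * s

  polys <- list()
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      polys[[length(polys) + 1]] <- list(
        class = "field",
        ring = rect_ring(x0 + (i - 1) * s, y0 + (j - 1) * s,
                         x0 + i * s, y0 + j * s)
      )
    }
  }
  # hedge strips straddle every internal field boundary, full grid span
  if (nx > 1) {
    for (i in seq_len(nx - 1)) {
      xc <- x0 + i * s
      polys[[length(polys) + 1]] <- list(
        class = "hedge",
        ring = rect_ring(xc - w / 2, y0, xc + w / 2, y1)
      )
    }
  }
  if (ny > 1) {
    for (j in seq_len(ny - 1)) {
      yc <- y0 + j * s
      polys[[length(polys) + 1]] <- list(
        class = "hedge",
        ring = rect_ring(x0, yc - w / 2, x1, yc + w / 2)
      )
    }
  }
  # road runs along the east side of the block, building beside it
  road_off <- 10
  road_w <- 6
  polys[[length(polys) + 1]] <- list(
    class = "road",
    ring = rect_ring(x1 + road_off, y0 - 40, x1 + road_off + road_w, y1 + 40)
  )
  polys[[length(polys) + 1]] <- list(
    class = "building",
    ring = rect_ring(x1 + road_off + road_w + 8, y0 + ny * s / 3,
                     x1 + road_off + road_w + 8 + 20, y0 + ny * s / 3 + 30)
  )

  margin <- 40
  out <- list(
    polygons = polys,
    bbox = c(xmin = x0 - margin, ymin = y0 - margin,
             xmax = x1 + margin, ymax = y1 + margin),
    sett = c(easting = unname(sett[["easting"]]),
             northing = unname(sett[["northing"]])),
    epsg = config$epsg
  )
  class(out) <- "badger_landscape"
  out
}

#' Feature classes present in a landscape
#' @param landscape a `badger_landscape`
#' @return character vector
#' @export
landscape_classes <- function(landscape) {
  sort(unique(vapply(landscape$polygons, `[[`, character(1), "class")))
}

#' @export
print.badger_landscape <- function(x, ...) {
  cls <- table(vapply(x$polygons, `[[`, character(1), "class"))
  cat("<badger_landscape> EPSG:", x$epsg, "\n  ",
      paste(sprintf("%s: %d", names(cls), as.integer(cls)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write a landscape as GeoJSON (WGS84 coordinates)
#'
#' Coordinates are stored in EPSG:4326 as GeoJSON requires; the projected
#' CRS actually used for analysis is recorded in each feature's properties
#' and in the top-level `properties` member. Output is byte-stable for a
#' given landscape (fixed 9-decimal coordinate formatting).
#'
#' @param landscape a `badger_landscape`
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_landscape_geojson <- function(landscape, path) {
  feats <- lapply(landscape$polygons, function(p) {
    ring <- close_ring(p$ring)
    ll <- utm_unproject(ring[, 1], ring[, 2], landscape$epsg)
    coords <- lapply(seq_len(nrow(ll)), function(i) {
      c(round(ll[i, "lon"], 9), round(ll[i, "lat"], 9))
    })
    list(
      type = "Feature",
      properties = list(class = p$class, projected_epsg = landscape$epsg),
      geometry = list(type = "Polygon", coordinates = list(coords))
    )
  })
  gj <- list(
    type = "FeatureCollection",
    properties = list(
      projected_epsg = landscape$epsg,
      sett_easting = round(unname(landscape$sett["easting"]), 3),
      sett_northing = round(unname(landscape$sett["northing"]), 3),
      bbox_projected = round(unname(landscape$bbox), 3)
    ),
    features = feats
  )
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = 9), path)
  invisible(path)
}

#' Read a landscape written by [write_landscape_geojson()]
#'
#' @param path GeoJSON file path
#' @return A `badger_landscape` with rings re-projected into the CRS
#'   recorded in the file's properties.
#' @export
read_landscape_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  epsg <- gj$properties$projected_epsg
  polys <- lapply(gj$features, function(f) {
    coords <- f$geometry$coordinates[[1]]
    lon <- vapply(coords, function(c2) c2[[1]], numeric(1))
    lat <- vapply(coords, function(c2) c2[[2]], numeric(1))
    en <- utm_project(lat, lon, epsg)
    list(class = f$properties$class,
         ring = cbind(en[, "easting"], en[, "northing"]))
  })
  out <- list(
    polygons = polys,
    bbox = c(xmin = gj$properties$bbox_projected[[1]],
             ymin = gj$properties$bbox_projected[[2]],
             xmax = gj$properties$bbox_projected[[3]],
             ymax = gj$properties$bbox_projected[[4]]),
    sett = c(easting = gj$properties$sett_easting,
             northing = gj$properties$sett_northing),
    epsg = epsg
  )
  class(out) <- "badger_landscape"
  out
}
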