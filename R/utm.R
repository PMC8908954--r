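# Transverse Mercator (UTM) forward/inverse on the WGS84 ellipsoid.
# Series expansions good to ~1 mm within a zone, which is far below the
# GPS error (~10 m) this package deals with.

.WGS84_A <- 6378137
.WGS84_F <- 1 / 298.257223563
.UTM_K0 <- 0.9996
.UTM_FE <- 500000

#' Central meridian (degrees) of a UTM zone
#' @param zone UTM zone number (1-60)
#' @keywords internal
utm_central_meridian <- function(zone) -183 + 6 * zone

.utm_zone_from_epsg <- function(epsg) {
  if (epsg >= 32601 && epsg <= 32660) return(epsg - 32600)
  if (epsg >= 32701 && epsg <= 32760) return(epsg - 32700)
  stop("unsupported EPSG code (expected a WGS84 UTM zone): ", epsg)
}

#' Project WGS84 coordinates to UTM
#'
#' Forward transverse Mercator projection onto the WGS84 ellipsoid using
#' standard series expansions. The default zone is 29N (EPSG:32629), the
#' projection used for all planar analyses in this package.
#'
#' @param lat,lon numeric vectors of geographic coordinates (degrees).
#' @param epsg EPSG code of a WGS84 UTM zone (default 32629).
#' @return A two-column matrix with columns `easting`, `northing` (metres).
#' @seealso [utm_unproject()]
#' @export
utm_project <- function(lat, lon, epsg = 32629) {
  zone <- .utm_zone_from_epsg(epsg)
  south <- epsg > 32700
  a <- .WGS84_A
  f <- .WGS84_F
  e2 <- f * (2 - f)
  ep2 <- e2 / (1 - e2)
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  lam0 <- utm_central_meridian(zone) * pi / 180

  N <- a / sqrt(1 - e2 * sin(phi)^2)
  Tt <- tan(phi)^2
  C <- ep2 * cos(phi)^2
  A <- (lam - lam0) * cos(phi)

  M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
    (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
    (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
    (35 * e2^3 / 3072) * sin(6 * phi))

  x <- .UTM_K0 * N * (A + (1 - Tt + C) * A^3 / 6 +
    (5 - 18 * Tt + Tt^2 + 72 * C - 58 * ep2) * A^5 / 120) + .UTM_FE
  y <- .UTM_K0 * (M + N * tan(phi) * (A^2 / 2 +
    (5 - Tt + 9 * C + 4 * C^2) * A^4 / 24 +
    (61 - 58 * Tt + Tt^2 + 600 * C - 330 * ep2) * A^6 / 720))
  if (south) y <- y + 10000000
  cbind(easting = x, northing = y)
}

#' Inverse-project UTM coordinates to WGS84
#'
#' @param easting,northing numeric vectors of projected coordinates (m).
#' @param epsg EPSG code of a WGS84 UTM zone (default 32629).
#' @return A two-column matrix with columns `lat`, `lon` (degrees).
#' @export
utm_unproject <- function(easting, northing, epsg = 32629) {
  zone <- .utm_zone_from_epsg(epsg)
  south <- epsg > 32700
  a <- .WGS84_A
  f <- .WGS84_F
  e2 <- f * (2 - f)
  ep2 <- e2 / (1 - e2)
  lam0 <- utm_central_meridian(zone) * pi / 180
  y <- if (south) northing - 10000000 else northing

  M <- y / .UTM_K0
  mu <- M / (a * (1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256))
  e1 <- (1 - sqrt(1 - e2)) / (1 + sqrt(1 - e2))
  phi1 <- mu + (3 * e1 / 2 - 27 * e1^3 / 32) * sin(2 * mu) +
    (21 * e1^2 / 16 - 55 * e1^4 / 32) * sin(4 * mu) +
    (151 * e1^3 / 96) * sin(6 * mu) +
    (1097 * e1^4 / 512) * sin(8 * mu)

  C1 <- ep2 * cos(phi1)^2
  T1 <- tan(phi1)^2
  N1 <- a / sqrt(1 - e2 * sin(phi1)^2)
  R1 <- a * (1 - e2) / (1 - e2 * sin(phi1)^2)^1.5
  D <- (easting - .UTM_FE) / (N1 * .UTM_K0)

  phi <- phi1 - (N1 * tan(phi1) / R1) * (D^2 / 2 -
    (5 + 3 * T1 + 10 * C1 - 4 * C1^2 - 9 * ep2) * D^4 / 24 +
    (61 + 90 * T1 + 298 * C1 + 45 * T1^2 - 252 * ep2 - 3 * C1^2) * D^6 / 720)
  lam <- lam0 + (D - (1 + 2 * T1 + C1) * D^3 / 6 +
    (5 - 2 * C1 + 28 * T1 - 3 * C1^2 + 8 * ep2 + 24 * T1^2) * D^5 / 120) /
    cos(phi1)

  cbind(lat = phi * 180 / pi, lon = lam * 180 / pi)
}
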