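# Small planar geometry kit: shoelace areas, ray-cast point-in-polygon,
# point-to-segment distances. Polygons are closed or open rings given as
# two-column matrices (easting, northing) in a projected frame.

#' Signed shoelace area of a polygon ring (m^2); positive if counter-clockwise
#' @keywords internal
ring_area_signed <- function(ring) {
  ring <- close_ring(ring)
  x <- ring[, 1]
  y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Ensure a ring's last vertex repeats its first
#' @keywords internal
close_ring <- function(ring) {
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

#' Ray-casting point-in-polygon test, vectorised over points
#'
#' Even-odd rule; points exactly on an edge may fall on either side, which
#' is immaterial at the 20 m buffer scales used here.
#' @param pts two-column matrix of points
#' @param ring two-column matrix of polygon vertices
#' @return logical vector
#' @keywords internal
points_in_ring <- function(pts, ring) {
  ring <- close_ring(ring)
  px <- pts[, 1]
  py <- pts[, 2]
  inside <- rep(FALSE, length(px))
  n <- nrow(ring)
  for (k in seq_len(n - 1)) {
    x1 <- ring[k, 1]; y1 <- ring[k, 2]
    x2 <- ring[k + 1, 1]; y2 <- ring[k + 1, 2]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py[crosses] - y1) / (y2 - y1) * (x2 - x1)
      hit <- which(crosses)[xint > px[crosses]]
      inside[hit] <- !inside[hit]
    }
  }
  inside
}

#' Squared distance from points to one segment, vectorised over points
#' @keywords internal
dist2_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  L2 <- dx * dx + dy * dy
  if (L2 == 0) return((px - x1)^2 + (py - y1)^2)
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2))
  (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
}

#' Which points lie within `radius` of a polygon (inside counts as 0 m)?
#'
#' Uses a bounding-box prefilter so that large point sets (40 Hz tracks)
#' only pay for exact tests near the polygon.
#' @param pts two-column matrix of projected points
#' @param ring polygon ring (two-column matrix)
#' @param radius buffer distance in metres
#' @return logical vector over points
#' @keywords internal
points_near_ring <- function(pts, ring, radius) {
  ring <- close_ring(ring)
  near <- rep(FALSE, nrow(pts))
  cand <- pts[, 1] >= min(ring[, 1]) - radius &
    pts[, 1] <= max(ring[, 1]) + radius &
    pts[, 2] >= min(ring[, 2]) - radius &
    pts[, 2] <= max(ring[, 2]) + radius
  if (!any(cand)) return(near)
  sub <- pts[cand, , drop = FALSE]
  ok <- points_in_ring(sub, ring)
  todo <- !ok
  if (any(todo)) {
    px <- sub[todo, 1]
    py <- sub[todo, 2]
    d2min <- rep(Inf, length(px))
    for (k in seq_len(nrow(ring) - 1)) {
      d2 <- dist2_point_segment(px, py, ring[k, 1], ring[k, 2],
                                ring[k + 1, 1], ring[k + 1, 2])
      d2min <- pmin(d2min, d2)
    }
    ok[todo] <- d2min <= radius^2
  }
  near[cand] <- ok
  near
}

#' Axis-aligned rectangle ring
#' @keywords internal
rect_ring <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin, xmin),
        c(ymin, ymin, ymax, ymax, ymin))
}

#' Area of a set of contour rings with even-odd hole handling (m^2)
#'
#' Rings whose first vertex is enclosed by an odd number of the other
#' rings are holes and subtract from the total.
#' @keywords internal
ring_set_area <- function(rings) {
  if (length(rings) == 0) return(0)
  areas <- vapply(rings, function(r) abs(ring_area_signed(r)), numeric(1))
  depth <- vapply(seq_along(rings), function(i) {
    p <- rings[[i]][1, , drop = FALSE]
    sum(vapply(seq_along(rings), function(j) {
      if (i == j) return(FALSE)
      points_in_ring(p, rings[[j]])
    }, logical(1)))
  }, numeric(1))
  sum(areas * ifelse(depth %% 2 == 0, 1, -1))
}
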