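#' Planar polygon utilities
#'
#' All geometry in gapscape is planar, in kilometres. Polygons are plain
#' two-column matrices of vertices (`x`, `y`), stored open (first vertex not
#' repeated). Polygon *sets* (protected areas, biomes) are tibbles with one
#' row per feature and a `geometry` list-column of such matrices.
#'
#' @name geometry
#' @keywords internal
NULL

#' Area of a simple polygon
#'
#' Shoelace formula; vertex order does not matter (absolute value taken).
#'
#' @param poly Two-column numeric matrix of vertices (open ring).
#' @return Area in squared input units.
#' @export
#' @examples
#' poly_area(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
poly_area <- function(poly) {
  if (is.null(poly) || nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

close_ring <- function(poly) {
  if (!all(poly[1, ] == poly[nrow(poly), ])) poly <- rbind(poly, poly[1, ])
  poly
}

#' Test points for polygon membership
#'
#' @param pts Two-column matrix (or data frame with `x`, `y`) of points.
#' @param poly Two-column vertex matrix.
#' @return Logical vector, one entry per point.
#' @export
points_in_poly <- function(pts, poly) {
  pts <- as_xy_matrix(pts)
  if (nrow(pts) == 0L) return(logical(0))
  mgcv::in.out(close_ring(as.matrix(poly)), pts)
}

#' Test points against a list of polygons
#'
#' @param pts Points as in [points_in_poly()].
#' @param polys List of vertex matrices (e.g. a `geometry` list-column).
#' @return Logical vector: `TRUE` where the point falls in at least one polygon.
#' @export
points_in_any <- function(pts, polys) {
  pts <- as_xy_matrix(pts)
  inside <- rep(FALSE, nrow(pts))
  for (p in polys) {
    todo <- which(!inside)
    if (length(todo) == 0L) break
    inside[todo] <- points_in_poly(pts[todo, , drop = FALSE], p)
  }
  inside
}

as_xy_matrix <- function(pts) {
  if (is.data.frame(pts)) pts <- cbind(pts$x, pts$y)
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  storage.mode(pts) <- "double"
  pts
}

#' Clip a polygon to an axis-aligned rectangle
#'
#' Sutherland-Hodgman clipping against the four half-planes of `extent`.
#'
#' @param poly Two-column vertex matrix.
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)`.
#' @return Clipped vertex matrix, possibly with 0 rows.
#' @export
clip_poly_rect <- function(poly, extent) {
  stopifnot(length(extent) == 4)
  clip_half <- function(pts, keep, intersect) {
    n <- nrow(pts)
    if (n == 0L) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n)) {
      a <- pts[i, ]; b <- pts[if (i == n) 1L else i + 1L, ]
      ka <- keep(a); kb <- keep(b)
      if (ka) out <- rbind(out, a)
      if (xor(ka, kb)) out <- rbind(out, intersect(a, b))
    }
    out
  }
  ix <- function(a, b, t) a + t * (b - a)
  p <- as.matrix(poly)
  p <- clip_half(p, function(q) q[1] >= extent[1],
                 function(a, b) ix(a, b, (extent[1] - a[1]) / (b[1] - a[1])))
  p <- clip_half(p, function(q) q[1] <= extent[2],
                 function(a, b) ix(a, b, (extent[2] - a[1]) / (b[1] - a[1])))
  p <- clip_half(p, function(q) q[2] >= extent[3],
                 function(a, b) ix(a, b, (extent[3] - a[2]) / (b[2] - a[2])))
  p <- clip_half(p, function(q) q[2] <= extent[4],
                 function(a, b) ix(a, b, (extent[4] - a[2]) / (b[2] - a[2])))
  unname(p)
}

#' Regular polygon approximating a disc
#'
#' @param cx,cy Centre coordinates.
#' @param r Circumradius.
#' @param n Number of vertices.
#' @param rot Rotation of the first vertex, radians.
#' @return Two-column vertex matrix.
#' @export
regular_poly <- function(cx, cy, r, n = 12L, rot = 0) {
  th <- rot + 2 * pi * (seq_len(n) - 1L) / n
  cbind(cx + r * cos(th), cy + r * sin(th))
}

#' Distance from points to a polygon
#'
#' Zero for points inside; otherwise the minimum distance to the boundary.
#'
#' @inheritParams points_in_poly
#' @return Numeric vector of distances.
#' @export
dist_to_poly <- function(pts, poly) {
  pts <- as_xy_matrix(pts)
  poly <- as.matrix(poly)
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1L), , drop = FALSE]
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(n)) {
    d <- pmin(d, point_seg_dist(pts, a[i, ], b[i, ]))
  }
  d[points_in_poly(pts, poly)] <- 0
  d
}

point_seg_dist <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2))
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((pts[, 1] - (a[1] + t * ab[1]))^2 + (pts[, 2] - (a[2] + t * ab[2]))^2)
}

#' Fraction of a protected area within reach of occurrence records
#'
#' Computes the share of a PA polygon lying within `radius` of at least one
#' occurrence record (the "sampled area": the union of record-centred discs
#' intersected with the PA). The union-of-discs area is evaluated by
#' deterministic grid sampling of the PA at a resolution fine relative to the
#' buffer radius, so the estimate is reproducible and monotone in the record
#' set.
#'
#' @param occurrences Data frame with `x`, `y` columns (any species).
#' @param pa_poly PA polygon vertex matrix.
#' @param radius Buffer radius around each record, km. Default 1 km, the mode
#'   of maximum collection distances reported for tropical survey work.
#' @param step Sampling step, km; default `radius / 5`, refined if the PA is
#'   small.
#' @return Proportion in \[0, 1\].
#' @export
sampled_area_fraction <- function(occurrences, pa_poly, radius = 1, step = NULL) {
  stopifnot(radius > 0)
  pa_poly <- as.matrix(pa_poly)
  if (poly_area(pa_poly) <= 0) {
    stop("sampled_area_fraction(): PA polygon has zero area")
  }
  bb <- c(range(pa_poly[, 1]), range(pa_poly[, 2]))
  if (is.null(step)) {
    # <= ~40k probe points, but never coarser than radius/5
    step <- max(radius / 5, sqrt((bb[2] - bb[1]) * (bb[4] - bb[3]) / 40000))
  }
  gx <- seq(bb[1] + step / 2, bb[2], by = step)
  gy <- seq(bb[3] + step / 2, bb[4], by = step)
  probes <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  inside <- points_in_poly(probes, pa_poly)
  probes <- probes[inside, , drop = FALSE]
  if (nrow(probes) == 0L) return(0)
  occ <- as_xy_matrix(occurrences)
  # only records able to reach the PA bounding box matter
  keep <- occ[, 1] >= bb[1] - radius & occ[, 1] <= bb[2] + radius &
    occ[, 2] >= bb[3] - radius & occ[, 2] <= bb[4] + radius
  occ <- occ[keep, , drop = FALSE]
  if (nrow(occ) == 0L) return(0)
  covered <- rep(FALSE, nrow(probes))
  r2 <- radius^2
  for (i in seq_len(nrow(occ))) {
    todo <- which(!covered)
    if (length(todo) == 0L) break
    dx <- probes[todo, 1] - occ[i, 1]
    dy <- probes[todo, 2] - occ[i, 2]
    covered[todo] <- dx * dx + dy * dy <= r2
  }
  mean(covered)
}

#' Record density of a region
#'
#' @param points Data frame or matrix of record coordinates; only points
#'   inside `region` are counted.
#' @param region Polygon vertex matrix.
#' @return Records per square kilometre.
#' @export
record_density <- function(points, region) {
  a <- poly_area(region)
  if (a <= 0) stop("record_density(): region has zero area")
  pts <- as_xy_matrix(points)
  if (nrow(pts) == 0L) return(0)
  sum(points_in_poly(pts, region)) / a
}

#' Classify a record density into map-legend bins
#'
#' Ordered log-decade bins: `[0]`, `(0,0.01]`, `(0.01,0.1]`, `(0.1,1]`,
#' `(1,10]`, `(10,130+]` records per square kilometre.
#'
#' @param density Numeric vector of non-negative densities.
#' @return Ordered factor of class labels.
#' @export
density_class <- function(density) {
  stopifnot(all(density >= 0))
  labs <- c("[0]", "(0,0.01]", "(0.01,0.1]", "(0.1,1]", "(1,10]", "(10,130+]")
  idx <- findInterval(density, c(0, 1e-12, 0.01, 0.1, 1, 10), left.open = TRUE)
  idx[density == 0] <- 1L
  idx <- pmin(pmax(idx, 1L), 6L)
  factor(labs[idx], levels = labs, ordered = TRUE)
}
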