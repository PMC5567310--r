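#' Build a hexagonal sampling grid
#'
#' Tessellates a rectangular extent with flat-top hexagons of the given
#' vertex-to-vertex diameter. The default of 55 km is the approximate ground
#' distance of a 0.5-degree cell, the unit size conventionally used so that a
#' species is neither assumed to occupy very large areas (coarser grids) nor
#' only very small ones (finer grids). Cell ids are assigned row-major
#' (bottom row first, left to right) and are stable for a given extent and
#' diameter. Because all hexagons share one size, the tessellation is the
#' Voronoi diagram of the cell centres: a point belongs to the cell with the
#' nearest centre, which is how [assign_to_cells()] resolves membership
#' (boundary ties go to the lowest cell id).
#'
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)` in km.
#' @param diameter Hexagon vertex-to-vertex diameter in km.
#' @return A `hex_grid` object: list with `cells` (tibble: `cell_id`, `cx`,
#'   `cy`, `geometry` list-column of vertex matrices), `diameter`, `extent`.
#' @export
#' @examples
#' g <- hex_grid(c(0, 200, 0, 200), diameter = 55)
#' nrow(g$cells)
hex_grid <- function(extent, diameter = 55) {
  stopifnot(length(extent) == 4, diameter > 0)
  w <- extent[2] - extent[1]; h <- extent[4] - extent[3]
  if (w <= 0 || h <= 0) stop("hex_grid(): empty extent")
  if (diameter > 2 * max(w, h)) {
    stop("hex_grid(): diameter exceeds extent dimensions")
  }
  R <- diameter / 2          # circumradius (flat-top: width = 2R)
  dy <- sqrt(3) * R          # row height
  dx <- 1.5 * R              # column pitch
  jj <- seq(-1L, ceiling(w / dx) + 1L)
  cx <- extent[1] + jj * dx
  centers <- do.call(rbind, lapply(seq_along(jj), function(k) {
    off <- if (jj[k] %% 2 == 0) 0 else dy / 2
    ii <- seq(-1L, ceiling((h + dy) / dy) + 1L)
    cy <- extent[3] + off + ii * dy
    cbind(cx[k], cy)
  }))
  # keep hexagons that actually intersect the extent; record clipped area
  clip_area <- vapply(seq_len(nrow(centers)), function(i) {
    cp <- clip_poly_rect(hex_vertices(centers[i, 1], centers[i, 2], R), extent)
    if (nrow(cp) >= 3) poly_area(cp) else 0
  }, numeric(1))
  keep <- clip_area > 1e-9
  centers <- centers[keep, , drop = FALSE]
  clip_area <- clip_area[keep]
  ord <- order(round(centers[, 2] / (dy / 2)) * (dy / 2), centers[, 1])
  centers <- centers[ord, , drop = FALSE]
  clip_area <- clip_area[ord]
  cells <- tibble::tibble(
    cell_id = seq_len(nrow(centers)),
    cx = centers[, 1],
    cy = centers[, 2],
    area = clip_area,
    geometry = lapply(seq_len(nrow(centers)), function(i) {
      hex_vertices(centers[i, 1], centers[i, 2], R)
    })
  )
  structure(
    list(cells = cells, diameter = diameter, extent = extent),
    class = "hex_grid"
  )
}

hex_vertices <- function(cx, cy, R) {
  th <- 2 * pi * (0:5) / 6   # flat-top: vertices at 0, 60, ..., 300 degrees
  cbind(cx + R * cos(th), cy + R * sin(th))
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf(
    "<hex_grid> %d cells, diameter %.1f km, extent [%g, %g] x [%g, %g]\n",
    nrow(x$cells), x$diameter, x$extent[1], x$extent[2], x$extent[3], x$extent[4]
  ))
  invisible(x)
}

#' Locate points on a hexagonal grid
#'
#' Nearest-centre lookup (exact for a uniform hexagonal tessellation);
#' ties on cell boundaries resolve to the lowest cell id.
#'
#' @param pts Matrix or data frame of `x`, `y`.
#' @param grid A [hex_grid()].
#' @return Integer vector of cell ids.
#' @keywords internal
hex_locate <- function(pts, grid) {
  pts <- as_xy_matrix(pts)
  ext <- grid$extent
  out_of <- pts[, 1] < ext[1] | pts[, 1] > ext[2] |
    pts[, 2] < ext[3] | pts[, 2] > ext[4]
  if (any(out_of)) {
    stop(sprintf(
      "points outside the gridded extent (first offending record: row %d at x=%g, y=%g)",
      which(out_of)[1], pts[which(out_of)[1], 1], pts[which(out_of)[1], 2]
    ))
  }
  cx <- grid$cells$cx; cy <- grid$cells$cy
  n <- nrow(pts)
  ids <- integer(n)
  chunk <- max(1L, floor(5e6 / length(cx)))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    d2 <- outer(pts[s:e, 1], cx, "-")^2 + outer(pts[s:e, 2], cy, "-")^2
    ids[s:e] <- max.col(-d2, ties.method = "first")
  }
  grid$cells$cell_id[ids]
}

#' Assign occurrence records to hexagonal grid cells
#'
#' Each record is placed in exactly one cell; the result carries both the
#' per-record assignment and, through [species_ranges()] /
#' [cell_record_counts()], the per-species occupied-cell sets and per-cell
#' record tallies that the endemism indices are built from.
#'
#' @param occurrences Tibble with `species_id`, `x`, `y` (and optionally
#'   `year`).
#' @param grid A [hex_grid()] covering every record.
#' @return The occurrence tibble with a `cell_id` column appended.
#' @export
assign_to_cells <- function(occurrences, grid) {
  stopifnot(is.data.frame(occurrences), inherits(grid, "hex_grid"))
  occurrences <- tibble::as_tibble(occurrences)
  occurrences$cell_id <- hex_locate(occurrences, grid)
  occurrences
}

#' Per-species occupied-cell sets
#'
#' @param assigned Output of [assign_to_cells()].
#' @return Tibble `species_id`, `cell_id` (distinct pairs), i.e. the species
#'   range in grid cells; `range_size` per species is
#'   `dplyr::count(species_id)` of this table.
#' @export
species_ranges <- function(assigned) {
  stopifnot("cell_id" %in% names(assigned))
  dplyr::distinct(
    dplyr::arrange(assigned[, c("species_id", "cell_id")], .data$species_id, .data$cell_id)
  )
}

#' Per-cell record counts
#'
#' @param assigned Output of [assign_to_cells()].
#' @param grid Optional [hex_grid()]; when given, cells with zero records are
#'   included.
#' @return Tibble `cell_id`, `n_records`.
#' @export
cell_record_counts <- function(assigned, grid = NULL) {
  counts <- dplyr::count(assigned, .data$cell_id, name = "n_records")
  if (!is.null(grid)) {
    counts <- dplyr::left_join(
      grid$cells[, "cell_id"], counts, by = "cell_id"
    )
    counts$n_records[is.na(counts$n_records)] <- 0L
  }
  dplyr::arrange(tibble::as_tibble(counts), .data$cell_id)
}

#' Identify grid cells overlapping protected areas
#'
#' A cell counts as overlapping a polygon when its centroid or any of its six
#' vertices falls inside the polygon, or any polygon vertex falls inside the
#' hexagon. With hexagons smaller than the polygon features this captures all
#' overlaps of non-negligible area.
#'
#' @param grid A [hex_grid()].
#' @param polys List of polygon vertex matrices (e.g. `pas$geometry`).
#' @return Integer vector of overlapping `cell_id`s.
#' @export
cells_overlapping <- function(grid, polys) {
  cells <- grid$cells
  hit <- rep(FALSE, nrow(cells))
  probe <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    rbind(c(cells$cx[i], cells$cy[i]), cells$geometry[[i]])
  }))
  probe_cell <- rep(seq_len(nrow(cells)), each = 7L)
  for (p in polys) {
    inside <- points_in_poly(probe, p)
    hit[unique(probe_cell[inside])] <- TRUE
  }
  # polygon vertices contained in hexagons
  verts <- do.call(rbind, lapply(polys, as.matrix))
  if (!is.null(verts) && nrow(verts) > 0) {
    ext <- grid$extent
    ok <- verts[, 1] >= ext[1] & verts[, 1] <= ext[2] &
      verts[, 2] >= ext[3] & verts[, 2] <= ext[4]
    if (any(ok)) {
      ids <- hex_locate(verts[ok, , drop = FALSE], grid)
      hit[match(ids, cells$cell_id)] <- TRUE
    }
  }
  sort(cells$cell_id[hit])
}
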