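#' Read and write occurrence records
#'
#' Plain CSV with columns `species_id`, `x`, `y` and optional `year`.
#'
#' @param path CSV file.
#' @return Tibble of occurrences.
#' @export
read_occurrences <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           species_id = readr::col_character(),
                           x = readr::col_double(),
                           y = readr::col_double(),
                           .default = readr::col_guess()
                         ))
  stopifnot(all(c("species_id", "x", "y") %in% names(out)))
  if (any(!is.finite(out$x)) || any(!is.finite(out$y))) {
    stop("read_occurrences(): non-finite coordinates")
  }
  out
}

#' @rdname read_occurrences
#' @param occurrences Occurrence tibble.
#' @export
write_occurrences <- function(occurrences, path) {
  readr::write_csv(occurrences, path)
  invisible(path)
}

#' Write a polygon set as GeoJSON
#'
#' Minimal planar GeoJSON (one Polygon feature per row; all non-geometry
#' columns become feature properties). Coordinates are the package's planar
#' km; no CRS is attached.
#'
#' @param polys Tibble with a `geometry` list-column of vertex matrices.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_polygons_geojson <- function(polys, path) {
  props <- polys[, setdiff(names(polys), "geometry"), drop = FALSE]
  features <- lapply(seq_len(nrow(polys)), function(i) {
    ring <- close_ring(as.matrix(polys$geometry[[i]]))
    list(
      type = "Feature",
      properties = as.list(props[i, , drop = FALSE]),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(j) {
          c(ring[j, 1], ring[j, 2])
        }))
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a GeoJSON polygon set
#'
#' @param path GeoJSON file written by [write_polygons_geojson()] (or any
#'   FeatureCollection of simple Polygons).
#' @return Tibble with property columns and a `geometry` list-column.
#' @export
read_polygons_geojson <- function(path) {
  js <- jsonlite::read_json(path)
  stopifnot(identical(js$type, "FeatureCollection"))
  rows <- lapply(js$features, function(f) {
    stopifnot(identical(f$geometry$type, "Polygon"))
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], function(p) {
      c(p[[1]], p[[2]])
    }))
    if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
    props <- tibble::as_tibble(lapply(f$properties, function(v) v %||% NA))
    props$geometry <- list(unname(ring))
    props
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a raster layer as ESRI ASCII grid
#'
#' @param mat Matrix with rows ordered bottom-to-top (matrix row 1 = lowest
#'   y), columns west-to-east.
#' @param path Output `.asc` file.
#' @param xll,yll Lower-left corner.
#' @param cellsize Cell edge.
#' @param nodata NODATA value.
#' @return `path`, invisibly.
#' @export
write_asc <- function(mat, path, xll = 0, yll = 0, cellsize = 1, nodata = -9999) {
  mat[is.na(mat)] <- nodata
  header <- c(
    sprintf("ncols %d", ncol(mat)),
    sprintf("nrows %d", nrow(mat)),
    sprintf("xllcorner %.10g", xll),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(mat[rev(seq_len(nrow(mat))), , drop = FALSE], 1, paste,
                collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file.
#' @return List with `mat` (rows bottom-to-top), `xll`, `yll`, `cellsize`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  mat <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  mat <- mat[rev(seq_len(nrow(mat))), , drop = FALSE]
  if (!is.null(hdr$nodata_value)) mat[mat == hdr$nodata_value] <- NA
  list(mat = mat, xll = hdr$xllcorner, yll = hdr$yllcorner,
       cellsize = hdr$cellsize)
}

#' Export a synthetic world to plain-text files
#'
#' Writes `occurrences.csv`, `pas.geojson`, `biomes.geojson`, one `env_*.asc`
#' per layer, `tree.nwk` and `truth.json` under `dir`.
#'
#' @param world A [generate_world()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_occurrences(world$occurrences, file.path(dir, "occurrences.csv"))
  write_polygons_geojson(world$pas, file.path(dir, "pas.geojson"))
  write_polygons_geojson(world$biomes, file.path(dir, "biomes.geojson"))
  env <- world$env
  for (k in seq_len(ncol(env$values))) {
    mat <- matrix(env$values[, k], env$ny, env$nx, byrow = TRUE)
    write_asc(mat, file.path(dir, sprintf("env_%02d.asc", k)),
              xll = env$xmin, yll = env$ymin, cellsize = env$cellsize)
  }
  writeLines(write_newick(world$tree), file.path(dir, "tree.nwk"))
  jsonlite::write_json(
    list(seed = world$config$seed, species = world$truth$species),
    file.path(dir, "truth.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA
  )
  invisible(dir)
}
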