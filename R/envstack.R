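#' Aligned environmental raster stack
#'
#' A light container for co-registered square-cell rasters on a planar
#' extent: a `ncell x nlayer` value matrix plus grid metadata. Cells are
#' ordered row-major from the bottom-left corner (x fastest).
#'
#' @param values Numeric matrix, one column per layer.
#' @param nx,ny Grid dimensions (columns, rows).
#' @param xmin,ymin Lower-left corner of the grid, km.
#' @param cellsize Cell edge, km.
#' @return An `env_stack` object.
#' @export
env_stack <- function(values, nx, ny, xmin, ymin, cellsize) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == nx * ny, cellsize > 0)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("env_%02d", seq_len(ncol(values)))
  }
  structure(
    list(values = values, nx = as.integer(nx), ny = as.integer(ny),
         xmin = xmin, ymin = ymin, cellsize = cellsize),
    class = "env_stack"
  )
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d x %d cells (%.1f km), %d layers\n",
              x$nx, x$ny, x$cellsize, ncol(x$values)))
  invisible(x)
}

#' Cell-centre coordinates of an environmental stack
#'
#' @param stack An [env_stack()].
#' @return Matrix `ncell x 2` of x, y centres (row-major from bottom-left).
#' @export
env_cell_centers <- function(stack) {
  ix <- rep(seq_len(stack$nx), times = stack$ny)
  iy <- rep(seq_len(stack$ny), each = stack$nx)
  cbind(stack$xmin + (ix - 0.5) * stack$cellsize,
        stack$ymin + (iy - 0.5) * stack$cellsize)
}

#' Locate points on an environmental grid
#'
#' @param stack An [env_stack()].
#' @param pts Matrix or data frame of `x`, `y`.
#' @return Integer cell indices.
#' @export
env_locate <- function(stack, pts) {
  pts <- as_xy_matrix(pts)
  ix <- pmin(stack$nx, pmax(1L, 1L + floor((pts[, 1] - stack$xmin) / stack$cellsize)))
  iy <- pmin(stack$ny, pmax(1L, 1L + floor((pts[, 2] - stack$ymin) / stack$cellsize)))
  out_of <- pts[, 1] < stack$xmin | pts[, 1] > stack$xmin + stack$nx * stack$cellsize |
    pts[, 2] < stack$ymin | pts[, 2] > stack$ymin + stack$ny * stack$cellsize
  if (any(out_of)) {
    stop(sprintf("env_locate(): point %d outside the raster extent", which(out_of)[1]))
  }
  as.integer((iy - 1L) * stack$nx + ix)
}

#' Principal components of the environmental layers
#'
#' PCA on the correlation matrix (layers standardized to unit variance) of
#' the stack; the first `n_axes` component scores are returned as a new
#' stack, the standard dimensionality reduction before fitting distribution
#' models to many collinear climatic layers.
#'
#' @param stack An [env_stack()] with at least `n_axes` layers and no
#'   constant layer.
#' @param n_axes Number of leading axes to keep (default 4).
#' @return An [env_stack()] of component scores with attributes `loadings`,
#'   `sdev` and `var_explained` (proportion per retained axis).
#' @export
pca_env <- function(stack, n_axes = 4) {
  v <- stack$values
  if (ncol(v) < n_axes) stop("pca_env(): fewer layers than requested axes")
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0)) {
    stop("pca_env(): constant layer(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(v, center = TRUE, scale. = TRUE)
  scores <- pc$x[, seq_len(n_axes), drop = FALSE]
  out <- env_stack(scores, stack$nx, stack$ny, stack$xmin, stack$ymin,
                   stack$cellsize)
  attr(out, "loadings") <- pc$rotation[, seq_len(n_axes), drop = FALSE]
  attr(out, "sdev") <- pc$sdev
  attr(out, "var_explained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_axes)]
  out
}
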