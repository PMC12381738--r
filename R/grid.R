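#' Cartesian grid for acoustic fields
#'
#' A regular 2D or 3D grid on which slowness, source and pressure fields are
#' sampled. The Born-series solver requires isotropic spacing (one scalar
#' voxel size `h` shared by all axes).
#'
#' @param shape Integer vector of extents per axis (length 2 or 3, each >= 8).
#' @param spacing Voxel size in metres: a scalar, or a vector equal along
#'   all axes.
#' @param origin Coordinate (m) of the first voxel centre per axis. Defaults
#'   to a grid centred on the coordinate origin.
#' @return An object of class `ust_grid` with fields `shape`, `spacing`
#'   (per-axis), `h` (scalar spacing) and `origin`.
#' @examples
#' g <- ust_grid(c(64, 64), spacing = 1.5e-3)
#' grid_coords(g, 1)[1:3]
#' @export
ust_grid <- function(shape, spacing, origin = NULL) {
  shape <- as.integer(shape)
  nd <- length(shape)
  if (!nd %in% c(2L, 3L)) stop("grid must have 2 or 3 axes")
  if (any(shape < 8L)) stop("all grid extents must be >= 8")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, nd)
  if (length(spacing) != nd || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be positive and finite, one value per axis")
  if (diff(range(spacing)) > 1e-12 * spacing[1])
    stop("the Born-series solver requires isotropic spacing")
  if (is.null(origin)) origin <- -(shape - 1) * spacing / 2
  origin <- as.numeric(origin)
  if (length(origin) != nd) stop("origin must have one coordinate per axis")
  structure(
    list(shape = shape, spacing = spacing, h = spacing[1], origin = origin),
    class = "ust_grid"
  )
}

#' @export
print.ust_grid <- function(x, ...) {
  cat(sprintf(
    "<ust_grid> %s voxels, h = %g mm, extent %s cm\n",
    paste(x$shape, collapse = " x "), x$h * 1e3,
    paste(sprintf("%.1f", x$shape * x$spacing * 1e2), collapse = " x ")
  ))
  invisible(x)
}

grid_ndim <- function(grid) length(grid$shape)

grid_nvox <- function(grid) prod(grid$shape)

#' Voxel-centre coordinates along one axis
#'
#' @param grid A [ust_grid()].
#' @param axis Axis index (1-based).
#' @return Numeric vector of coordinates in metres.
#' @export
grid_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

grids_equal <- function(a, b) {
  identical(a$shape, b$shape) &&
    max(abs(a$spacing - b$spacing)) < 1e-12 &&
    max(abs(a$origin - b$origin)) < 1e-9
}

stop_if_grid_mismatch <- function(a, b, what = "fields") {
  if (!grids_equal(a, b)) stop(sprintf("%s are defined on different grids", what))
}
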