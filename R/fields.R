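#' Slowness field (reciprocal sound speed)
#'
#' The unknown of the inversion: slowness s = 1/c in s/m sampled on a grid.
#' Values must correspond to sound speeds within a physiological sanity
#' window of 500-3000 m/s.
#'
#' @param grid A [ust_grid()].
#' @param values Numeric array matching `grid$shape`, in s/m, or a scalar
#'   (replicated). Convenience: use [slowness_from_speed()] for m/s input.
#' @return A `slowness_field` object with fields `grid` and `values`.
#' @export
slowness_field <- function(grid, values) {
  if (length(values) == 1L) values <- array(values, dim = grid$shape)
  values <- as_field_array(values, grid)
  if (any(!is.finite(values))) stop("slowness values must be finite")
  if (any(values <= 0)) stop("slowness values must be positive")
  c_range <- range(1 / values)
  if (c_range[1] < 500 || c_range[2] > 3000)
    stop("implied sound speed outside the sanity window [500, 3000] m/s")
  structure(list(grid = grid, values = values), class = "slowness_field")
}

#' @rdname slowness_field
#' @param speed_m_s Sound speed array (m/s) matching the grid, or a scalar.
#' @export
slowness_from_speed <- function(grid, speed_m_s) {
  if (length(speed_m_s) == 1L) speed_m_s <- array(speed_m_s, dim = grid$shape)
  slowness_field(grid, 1 / speed_m_s)
}

#' Sound speed map of a slowness field
#'
#' @param s A [slowness_field()].
#' @return Array of sound speed in m/s with the grid's shape.
#' @export
sound_speed <- function(s) 1 / s$values

#' Complex source field (Helmholtz right-hand side)
#'
#' @param grid A [ust_grid()].
#' @param values Complex (or numeric) array matching the grid shape.
#' @return A `source_field` object.
#' @export
source_field <- function(grid, values) {
  values <- as_field_array(values, grid, complex_ok = TRUE)
  if (any(!is.finite(Re(values))) || any(!is.finite(Im(values))))
    stop("source values must be finite")
  structure(list(grid = grid, values = values), class = "source_field")
}

#' @export
print.slowness_field <- function(x, ...) {
  cat(sprintf(
    "<slowness_field> sound speed %.1f-%.1f m/s on %s grid\n",
    min(1 / x$values), max(1 / x$values), paste(x$grid$shape, collapse = "x")
  ))
  invisible(x)
}

# Coerce to an array with the grid's dim, preserving complex type if allowed.
as_field_array <- function(values, grid, complex_ok = FALSE) {
  if (is.null(dim(values))) {
    if (length(values) != grid_nvox(grid))
      stop("field length does not match the grid")
    dim(values) <- grid$shape
  }
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("field dimensions do not match the grid")
  if (complex_ok) {
    storage.mode(values) <- "complex"
  } else {
    if (is.complex(values)) stop("field must be real-valued")
    storage.mode(values) <- "double"
  }
  values
}

helmholtz_solution <- function(grid, omega, values, residual, iterations) {
  structure(
    list(grid = grid, omega = omega, values = values,
         residual = residual, iterations = iterations),
    class = "helmholtz_solution"
  )
}

#' @export
print.helmholtz_solution <- function(x, ...) {
  cat(sprintf(
    "<helmholtz_solution> f = %.1f kHz, %s grid, residual %.2e (%d iterations)\n",
    x$omega / (2 * pi) / 1e3, paste(x$grid$shape, collapse = "x"),
    x$residual, x$iterations
  ))
  invisible(x)
}
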