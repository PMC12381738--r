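#' Multi-row ring-array geometry
#'
#' Describes a cylindrical array of point transducer elements: `n_rows`
#' identical rings of `n_elements_per_row` elements, stacked with
#' `row_pitch` between rows and centred symmetrically about the mid-plane
#' (z = `center[3]`). The defaults are a 22-cm diameter array of 32 rows by
#' 256 circumferential elements with 2.4 mm row pitch, i.e. 8192 elements.
#'
#' @param radius Ring radius in metres.
#' @param n_rows Number of element rows (1 for a classic single-ring array).
#' @param n_elements_per_row Circumferential elements per row (>= 3).
#' @param row_pitch Vertical spacing between rows in metres.
#' @param center Coordinates (m) of the array centre; length 2 for planar
#'   (single-ring, 2D) use, length 3 otherwise.
#' @return A `ring_array` object.
#' @examples
#' ring_array()                         # the full 256 x 32 array
#' ring_array(0.036, n_rows = 8, n_elements_per_row = 32, row_pitch = 4.8e-3)
#' @export
ring_array <- function(radius = 0.11, n_rows = 32L, n_elements_per_row = 256L,
                       row_pitch = 2.4e-3, center = c(0, 0, 0)) {
  if (radius <= 0) stop("radius must be positive")
  if (n_rows < 1) stop("n_rows must be >= 1")
  if (n_elements_per_row < 3) stop("n_elements_per_row must be >= 3")
  if (n_rows > 1 && row_pitch <= 0) stop("row_pitch must be positive")
  structure(
    list(radius = radius, n_rows = as.integer(n_rows),
         n_elements_per_row = as.integer(n_elements_per_row),
         row_pitch = row_pitch, center = as.numeric(center)),
    class = "ring_array"
  )
}

#' @export
print.ring_array <- function(x, ...) {
  cat(sprintf(
    "<ring_array> %d rows x %d elements (%d total), diameter %.1f cm, row pitch %.1f mm\n",
    x$n_rows, x$n_elements_per_row, x$n_rows * x$n_elements_per_row,
    2 * x$radius * 1e2, x$row_pitch * 1e3
  ))
  invisible(x)
}

#' Element positions of a ring array
#'
#' Element (r, j) sits at azimuth `2*pi*j / n_elements_per_row` (j from 0)
#' on a circle of the array radius, at row height `z_r`; heights are
#' symmetric about the array centre with the row pitch. Elements are ordered
#' row-major with azimuth varying fastest, so row r occupies rows
#' `(r-1)*n_elements_per_row + 1 : r*n_elements_per_row` of the matrix.
#'
#' @param spec A [ring_array()].
#' @return Numeric matrix with one row per element and columns x, y (and z
#'   for multi-row arrays / 3D use) in metres, plus attributes `row` and
#'   `azimuth_index`.
#' @export
element_positions <- function(spec) {
  nel <- spec$n_elements_per_row
  theta <- 2 * pi * (seq_len(nel) - 1) / nel
  xy <- cbind(spec$center[1] + spec$radius * cos(theta),
              spec$center[2] + spec$radius * sin(theta))
  z0 <- if (length(spec$center) >= 3) spec$center[3] else 0
  heights <- z0 + (seq_len(spec$n_rows) - (spec$n_rows + 1) / 2) * spec$row_pitch
  pos <- do.call(rbind, lapply(heights, function(z) cbind(xy, z)))
  attr(pos, "row") <- rep(seq_len(spec$n_rows), each = nel)
  attr(pos, "azimuth_index") <- rep(seq_len(nel) - 1L, spec$n_rows)
  colnames(pos) <- c("x", "y", "z")
  pos
}

#' Transmit set: which circumferential elements fire
#'
#' Each cylindrical-wave transmit fires the same azimuthal element index in
#' every row simultaneously. Defaults to all `n_elements_per_row` azimuths.
#'
#' @param spec A [ring_array()].
#' @param indices 0-based azimuthal element indices; unique, each
#'   `< n_elements_per_row`.
#' @return A `transmit_set` (integer vector with class).
#' @export
transmit_set <- function(spec, indices = seq_len(spec$n_elements_per_row) - 1L) {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("transmit indices must be unique")
  if (any(indices < 0) || any(indices >= spec$n_elements_per_row))
    stop("transmit indices must lie in [0, n_elements_per_row)")
  structure(indices, class = "transmit_set")
}

#' Sampling operator K: fields at element positions
#'
#' Builds the linear operator that extracts the pressure field at each array
#' element, treating elements as ideal points. Off-grid positions are
#' handled by a trilinear (bilinear in 2D) interpolation stencil whose
#' weights sum to one; `stencil = "nearest"` snaps to the closest voxel
#' instead. The same stencil deposits sources, so K and its transpose are
#' exact adjoints.
#'
#' @param spec A [ring_array()].
#' @param grid A [ust_grid()]. For a 2D grid, the array must be single-row.
#' @param stencil `"linear"` (default) or `"nearest"`.
#' @return A `sampling_operator` with per-element voxel indices and weights.
#' @export
sampling_operator <- function(spec, grid, stencil = c("linear", "nearest")) {
  stencil <- match.arg(stencil)
  pos <- element_positions(spec)
  row <- attr(pos, "row")
  az <- attr(pos, "azimuth_index")
  nd <- grid_ndim(grid)
  if (nd == 2) {
    if (spec$n_rows != 1L)
      stop("a 2D grid supports only single-row arrays")
    pos <- pos[, 1:2, drop = FALSE]
  }
  st <- point_stencils(pos, grid, stencil)
  structure(
    list(spec = spec, grid = grid, stencil = stencil,
         positions = pos, row = row, azimuth_index = az,
         idx = st$idx, w = st$w, n_elements = nrow(pos)),
    class = "sampling_operator"
  )
}

# Interpolation stencils for arbitrary points: linear index matrix [point,
# corner] into the grid array plus matching weights.
point_stencils <- function(pos, grid, stencil) {
  nd <- grid_ndim(grid)
  np <- nrow(pos)
  frac <- sapply(seq_len(nd), function(a)
    (pos[, a] - grid$origin[a]) / grid$spacing[a])
  if (is.null(dim(frac))) frac <- matrix(frac, nrow = np)
  if (stencil == "nearest") {
    i0 <- round(frac)
    if (any(i0 < 0) || any(i0 > rep(grid$shape - 1L, each = np)))
      stop("element position falls outside the grid")
    idx <- matrix(linear_index(i0, grid$shape), ncol = 1)
    return(list(idx = idx, w = matrix(1, nrow = np, ncol = 1)))
  }
  i0 <- floor(frac)
  f <- frac - i0
  if (any(i0 < 0) || any(i0 + 1 > rep(grid$shape - 1L, each = np)))
    stop("element position falls outside the grid interior")
  corners <- as.matrix(expand.grid(rep(list(0:1), nd)))
  idx <- matrix(0L, nrow = np, ncol = nrow(corners))
  w <- matrix(0, nrow = np, ncol = nrow(corners))
  for (k in seq_len(nrow(corners))) {
    off <- corners[k, ]
    idx[, k] <- linear_index(sweep(i0, 2, off, `+`), grid$shape)
    wk <- rep(1, np)
    for (a in seq_len(nd))
      wk <- wk * (if (off[a] == 1) f[, a] else 1 - f[, a])
    w[, k] <- wk
  }
  list(idx = idx, w = w)
}

linear_index <- function(i0, shape) {
  nd <- length(shape)
  out <- i0[, 1] + 1
  stride <- 1
  for (a in seq_len(nd - 1)) {
    stride <- stride * shape[a]
    out <- out + i0[, a + 1] * stride
  }
  as.integer(out)
}

#' Sample a field at the array elements
#'
#' Applies K: per-element complex pressure via the interpolation stencil.
#'
#' @param K A [sampling_operator()].
#' @param u A `helmholtz_solution` (or any field object with `grid` and
#'   `values`).
#' @return Complex vector of length `K$n_elements`.
#' @export
sample_field <- function(K, u) {
  stop_if_grid_mismatch(K$grid, u$grid, "operator and field")
  v <- u$values
  rowSums(matrix(v[K$idx], nrow = nrow(K$idx)) * K$w)
}

#' Inject element residuals into the grid (K transpose)
#'
#' The exact adjoint of [sample_field()]: each element's value is deposited
#' at its stencil voxels with the stencil weights.
#'
#' @param K A [sampling_operator()].
#' @param residual Complex vector, one value per element.
#' @return A [source_field()] on the operator's grid.
#' @export
inject <- function(K, residual) {
  if (length(residual) != K$n_elements)
    stop(sprintf("residual has length %d but the array has %d elements",
                 length(residual), K$n_elements))
  v <- array(0i, dim = K$grid$shape)
  contrib <- K$w * residual   # recycles residual down columns
  idx <- as.vector(K$idx)
  re <- rowsum(as.vector(Re(contrib)), idx)
  im <- rowsum(as.vector(Im(contrib)), idx)
  at <- as.integer(rownames(re))
  v[at] <- complex(real = re[, 1], imaginary = im[, 1])
  source_field(K$grid, v)
}

#' Cylindrical-wave transmit source
#'
#' One cylindrical-wave transmit fires the same circumferential element in
#' every row simultaneously: the source is the sum of unit-amplitude point
#' sources, one per row at the transmit azimuth, deposited on the grid with
#' the sampling operator's stencil (sources and receivers share the stencil
#' so K and K^T stay exact transposes).
#'
#' @param K A [sampling_operator()] built for the acquisition grid.
#' @param transmit_index 0-based azimuthal element index.
#' @return A [source_field()].
#' @export
make_cylindrical_source <- function(K, transmit_index) {
  spec <- K$spec
  if (transmit_index < 0 || transmit_index >= spec$n_elements_per_row)
    stop("transmit_index must lie in [0, n_elements_per_row)")
  az <- K$azimuth_index
  sel <- which(az == transmit_index)
  amp <- complex(length(az))
  amp[sel] <- 1 + 0i
  inject(K, amp)
}
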