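#' Settings for the convergent Born-series Helmholtz solver
#'
#' The solver iterates a preconditioned fixed-point scheme whose contraction
#' is guaranteed when the damping `epsilon` dominates the scattering
#' potential, `epsilon >= max |k(x)^2 - k0^2|`. The background wavenumber
#' squared `k0^2` is placed at the midpoint of the range of Re(k^2) and
#' `epsilon` is set from the contraction bound with a small safety margin;
#' both may be overridden.
#'
#' The computational domain is the field grid extended by an absorbing layer
#' of `pad_width` voxels per side (at least one wavelength when `pad_width`
#' is `NULL`), where the squared wavenumber acquires an imaginary part rising
#' with a cosine-squared taper to `absorption * k_pad^2` at the outer
#' boundary. The layer is closed periodically, which is what makes the
#' FFT-applied background Green's operator exact for the same discrete
#' operator the sparse oracle assembles.
#'
#' @param tolerance Relative-residual stopping threshold for ||Au - d||/||d||.
#' @param max_iterations Iteration cap; exceeding it is an error.
#' @param pad_width Absorbing-layer thickness in voxels per side, or `NULL`
#'   to use one wavelength at the background speed.
#' @param absorption Peak absorption strength relative to the background
#'   k^2 (dimensionless).
#' @param pad_slowness Slowness (s/m) filling the absorbing layer, or `NULL`
#'   to use the median slowness on the grid boundary. Fix it explicitly when
#'   gradients of a cost function are taken, so the layer does not move with
#'   the model.
#' @param k0_sq,epsilon Optional overrides of the background wavenumber
#'   squared (rad^2/m^2) and damping. `epsilon` below the contraction bound
#'   is an error.
#' @param method `"born"` (FFT Born series) or `"direct"` (sparse LU on the
#'   identical operator; small grids only).
#' @param check_every Residual check cadence in iterations.
#' @return A `born_settings` object.
#' @export
born_settings <- function(tolerance = 1e-6, max_iterations = 1000L,
                          pad_width = NULL, absorption = 1,
                          pad_slowness = NULL, k0_sq = NULL, epsilon = NULL,
                          method = c("born", "direct"), check_every = 4L) {
  method <- match.arg(method)
  if (tolerance <= 0) stop("tolerance must be positive")
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  if (!is.null(pad_width) && pad_width < 2) stop("pad_width must be >= 2 voxels")
  if (absorption <= 0) stop("absorption must be positive")
  structure(
    list(tolerance = tolerance, max_iterations = as.integer(max_iterations),
         pad_width = pad_width, absorption = absorption,
         pad_slowness = pad_slowness, k0_sq = k0_sq, epsilon = epsilon,
         method = method, check_every = as.integer(check_every)),
    class = "born_settings"
  )
}

# Padded heterogeneous system shared by the series solver and the sparse
# oracle: complex k^2 on the padded periodic grid, plus the series constants.
make_padded_system <- function(slowness, omega, settings) {
  grid <- slowness$grid
  nd <- grid_ndim(grid)
  h <- grid$h
  if (omega <= 0) stop("omega must be positive")

  s <- slowness$values
  pad_s <- settings$pad_slowness
  if (is.null(pad_s)) pad_s <- stats::median(s[boundary_mask(grid$shape)])
  k_bg <- omega * pad_s

  pad <- settings$pad_width
  if (is.null(pad)) pad <- ceiling(2 * pi / (k_bg * h))   # one wavelength
  pad <- max(2L, as.integer(pad))

  # sampling check: >= 4 points per minimum wavelength, warn at 4-6
  ppw <- 2 * pi / (omega * max(s) * h)
  if (ppw < 4)
    warning(sprintf("grid sampling is %.1f points per wavelength (< 4): solution will be inaccurate", ppw))

  # round each padded extent up to an FFT-friendly (5-smooth) length by
  # deepening the high-side pad
  pad_lo <- rep(pad, nd)
  pshape <- vapply(grid$shape + 2L * pad, next_fast_len, integer(1))
  pad_hi <- pshape - grid$shape - pad_lo

  k2 <- array(complex(real = (omega * pad_s)^2, imaginary = 0), dim = pshape)
  interior <- lapply(seq_len(nd), function(a) pad_lo[a] + seq_len(grid$shape[a]))
  k2_int <- (omega * s)^2
  if (nd == 2) k2[interior[[1]], interior[[2]]] <- k2_int
  else k2[interior[[1]], interior[[2]], interior[[3]]] <- k2_int

  # cosine-squared absorption taper, combined across axes by the deepest pad
  w <- pad_taper(pshape, pad_lo, pad_hi)
  k2 <- k2 + 1i * settings$absorption * k_bg^2 * w

  k0_sq <- settings$k0_sq
  if (is.null(k0_sq)) k0_sq <- (min(Re(k2)) + max(Re(k2))) / 2
  bound <- max(Mod(k2 - k0_sq))
  eps <- settings$epsilon
  if (is.null(eps)) eps <- 1.05 * bound
  if (eps < bound * (1 - 1e-12))
    stop(sprintf("epsilon %.4g violates the contraction bound %.4g", eps, bound))

  list(grid = grid, omega = omega, h = h, pad = pad, pshape = pshape,
       pad_lo = pad_lo, pad_hi = pad_hi,
       interior = interior, k2 = k2, k0_sq = k0_sq, eps = eps,
       n = prod(pshape))
}

# Smallest 5-smooth integer >= n (fast lengths for the mixed-radix FFT).
next_fast_len <- function(n) {
  n <- as.integer(n)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# Fractional depth into the absorbing layer, tapered by cos^2; 0 in the
# interior, 1 at the outer boundary. Per-axis ramps combined by max.
pad_taper <- function(pshape, pad_lo, pad_hi) {
  nd <- length(pshape)
  ramp <- function(n, lo, hi) {
    i <- seq_len(n)
    pmax((1 - cos(pi * pmax(0, lo + 1 - i) / lo)) / 2,
         (1 - cos(pi * pmax(0, i - (n - hi)) / hi)) / 2)
  }
  w <- array(0, dim = pshape)
  for (a in seq_len(nd))
    w <- pmax(w, aperm_broadcast(ramp(pshape[a], pad_lo[a], pad_hi[a]), a, pshape))
  w
}

# Broadcast a 1D profile along axis `a` of an array of shape `pshape`.
aperm_broadcast <- function(v, a, pshape) {
  array(v[slice.index(array(0L, pshape), a)], dim = pshape)
}

boundary_mask <- function(shape) {
  nd <- length(shape)
  m <- array(FALSE, dim = shape)
  for (a in seq_len(nd)) {
    idx <- as.list(rep(TRUE, nd))
    idx[[a]] <- c(1L, shape[a])
    m <- do.call(`[<-`, c(list(m), idx, list(TRUE)))
  }
  m
}

# Symbol of the periodic second-order central-difference Laplacian (positive
# semi-definite convention: this is -Laplacian's eigenvalues).
fd_laplacian_symbol <- function(pshape, h) {
  nd <- length(pshape)
  ell <- array(0, dim = pshape)
  for (a in seq_len(nd)) {
    m <- 0:(pshape[a] - 1)
    sa <- (4 / h^2) * sin(pi * m / pshape[a])^2
    ell <- ell + aperm_broadcast(sa, a, pshape)
  }
  ell
}

fftn <- function(x) stats::fft(x)
ifftn <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Apply the discrete operator A = Laplacian + diag(k^2) on the padded grid.
apply_padded_operator <- function(sys, u) {
  ifftn(fftn(u) * (-sys$ell)) + sys$k2 * u
}

pad_array <- function(x, sys) {
  out <- array(0i, dim = sys$pshape)
  idx <- sys$interior
  if (length(idx) == 2) out[idx[[1]], idx[[2]]] <- x
  else out[idx[[1]], idx[[2]], idx[[3]]] <- x
  out
}

crop_array <- function(x, sys) {
  idx <- sys$interior
  if (length(idx) == 2) x[idx[[1]], idx[[2]], drop = FALSE]
  else x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Solve the heterogeneous Helmholtz equation
#'
#' Solves `(Laplacian + omega^2 s^2) u = delta` on the field grid extended by
#' an absorbing layer, using the convergent Born series: the background
#' Green's operator `(Laplacian + k0^2 + i eps)^-1` is applied exactly by FFT
#' (with the finite-difference symbol, so the series solves the identical
#' sparse operator assembled by [assemble_direct_operator()]), and the
#' preconditioned iteration contracts whenever
#' `eps >= max |k^2 - k0^2|`. With `method = "direct"` in the settings the
#' same system is solved by sparse LU instead (small grids only).
#'
#' @param slowness A [slowness_field()].
#' @param omega Angular frequency in rad/s.
#' @param source A [source_field()] on the same grid.
#' @param settings A [born_settings()].
#' @return A `helmholtz_solution` with the complex pressure on the field
#'   grid (absorbing layer cropped), the achieved relative residual and the
#'   iteration count.
#' @examples
#' g <- ust_grid(c(32, 32), spacing = 1.5e-3)
#' s <- slowness_from_speed(g, 1500)
#' src <- source_field(g, {v <- array(0, g$shape); v[16, 16] <- 1; v})
#' u <- solve_helmholtz(s, 2 * pi * 150e3, src, born_settings())
#' @export
solve_helmholtz <- function(slowness, omega, source, settings = born_settings()) {
  stopifnot(inherits(slowness, "slowness_field"), inherits(source, "source_field"))
  stop_if_grid_mismatch(slowness$grid, source$grid)
  if (any(!is.finite(Mod(source$values))) || any(!is.finite(slowness$values)))
    stop("inputs contain NaN or Inf")
  sys <- make_padded_system(slowness, omega, settings)
  if (all(source$values == 0))
    return(helmholtz_solution(slowness$grid, omega,
                              array(0i, dim = slowness$grid$shape), 0, 0L))
  if (settings$method == "direct") {
    op <- assemble_direct_operator(slowness, omega, settings)
    return(direct_solution(op, source, omega))
  }
  sys$ell <- fd_laplacian_symbol(sys$pshape, sys$h)
  born_iterate(sys, pad_array(source$values, sys), settings, omega)
}

born_iterate <- function(sys, delta, settings, omega) {
  gker <- 1 / (-sys$ell + sys$k0_sq + 1i * sys$eps)
  V <- sys$k2 - sys$k0_sq - 1i * sys$eps
  pref <- (1i / sys$eps) * V
  dnorm <- sqrt(sum(Mod(delta)^2))
  u <- array(0i, dim = sys$pshape)
  res <- Inf
  it <- 0L
  history <- numeric(0)
  while (it < settings$max_iterations) {
    it <- it + 1L
    Gd <- ifftn(fftn(delta - V * u) * gker)
    u <- u + pref * (Gd - u)
    if (it %% settings$check_every == 0L || it == settings$max_iterations) {
      r <- apply_padded_operator(sys, u) - delta
      res <- sqrt(sum(Mod(r)^2)) / dnorm
      history <- c(history, res)
      if (!is.finite(res)) stop("Born series diverged (non-finite residual)")
      if (res <= settings$tolerance) break
    }
  }
  if (res > settings$tolerance)
    stop(sprintf("Born series did not converge in %d iterations (residual %.3e)",
                 it, res))
  out <- helmholtz_solution(sys$grid, omega, crop_array(u, sys), res, it)
  out$residual_history <- history
  out
}

#' Solve the adjoint Helmholtz system
#'
#' Returns `lambda` with `A^H lambda = rhs`. The discrete operator is
#' complex-symmetric (`A^T = A`), so `A^H = conj(A)` and the adjoint solve
#' reduces to a forward solve on the conjugated right-hand side:
#' `lambda = conj(A^-1 conj(rhs))`. One solver code path serves both.
#'
#' @inheritParams solve_helmholtz
#' @param rhs A [source_field()] holding the adjoint right-hand side.
#' @return A `helmholtz_solution` holding lambda.
#' @export
solve_helmholtz_adjoint <- function(slowness, omega, rhs, settings = born_settings()) {
  conj_rhs <- source_field(rhs$grid, Conj(rhs$values))
  fwd <- solve_helmholtz(slowness, omega, conj_rhs, settings)
  fwd$values <- Conj(fwd$values)
  fwd
}
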