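# Shared in-code fixtures for the test suite. Everything is generated
# deterministically at test time; no binary data ships with the package.

# Smooth random sound-speed map in [c_min, c_max] m/s on a 2D grid.
smooth_speed_map <- function(shape, c_min = 1400, c_max = 1600, sigma = 3,
                             seed = 1) {
  set.seed(seed)
  r <- array(stats::rnorm(prod(shape)), dim = shape)
  sm <- ringfwi:::gaussian_smooth(r, sigma)
  sm <- (sm - min(sm)) / (max(sm) - min(sm))
  c_min + (c_max - c_min) * sm
}

point_source <- function(grid, at = NULL, amp = 1 + 0i) {
  v <- array(0i, dim = grid$shape)
  if (is.null(at)) at <- ceiling(grid$shape / 2)
  v[matrix(at, nrow = 1)] <- amp
  source_field(grid, v)
}

# Dense matrix representation of a sampling operator (tiny grids only).
dense_K <- function(K) {
  n <- prod(K$grid$shape)
  M <- matrix(0, nrow = K$n_elements, ncol = n)
  for (e in seq_len(K$n_elements)) M[e, K$idx[e, ]] <- K$w[e, ]
  M
}

rel_l2 <- function(a, b) sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))

# Small single-ring 2D acquisition on a 9.6 cm grid.
toy_ring_2d <- function(n = 64, h = 1.5e-3, radius = 0.04, nel = 32) {
  g <- ust_grid(c(n, n), spacing = h)
  spec <- ring_array(radius, n_rows = 1, n_elements_per_row = nel,
                     center = c(0, 0))
  list(grid = g, spec = spec, K = sampling_operator(spec, g))
}
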