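#' Parametric synthetic breast phantom specification
#'
#' Describes a numerical breast immersed in a water bath: an outer ellipsoid
#' of subcutaneous fat, an optional skin shell, smooth fibroglandular blobs
#' and spherical lesions, all smoothed by a Gaussian of length
#' `smoothing_m` before conversion to slowness. Sound speeds default to
#' water 1500, fat 1440, fibroglandular tissue 1560, lesions 1580 and skin
#' 1600 m/s, i.e. tissue-like contrasts inside the 1400-1600 m/s display
#' window typical of breast sound-speed imaging.
#'
#' With `seed` fixed, generation is fully deterministic; `n_blobs` random
#' fibroglandular blobs are drawn inside the breast when `blobs` is `NULL`.
#'
#' @param breast_semiaxes Ellipsoid semi-axes (m), length 2 or 3.
#' @param breast_center Centre (m), same length as the semi-axes.
#' @param c_water,c_fat,c_fibroglandular,c_lesion,c_skin Sound speeds (m/s);
#'   all must lie in [1300, 1700].
#' @param skin_thickness Skin shell thickness (m); 0 disables the shell.
#' @param blobs Optional list of fibroglandular blobs, each
#'   `list(center=, radii=, speed=)` (radii per axis, m); `NULL` draws
#'   `n_blobs` at random.
#' @param lesions List of spheres `list(center=, radius=, speed=)`; must lie
#'   inside the breast.
#' @param n_blobs Number of random blobs when `blobs` is `NULL`.
#' @param smoothing_m Gaussian smoothing length (m).
#' @param seed Integer seed controlling random blob placement.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(breast_semiaxes = c(0.033, 0.033, 0.030),
                         breast_center = NULL,
                         c_water = 1500, c_fat = 1440,
                         c_fibroglandular = 1560, c_lesion = 1580,
                         c_skin = 1600, skin_thickness = 0,
                         blobs = NULL, lesions = list(),
                         n_blobs = 3L, smoothing_m = 2e-3, seed = 1L) {
  speeds <- c(c_water, c_fat, c_fibroglandular, c_lesion, c_skin)
  if (any(speeds < 1300) || any(speeds > 1700))
    stop("all tissue sound speeds must lie in [1300, 1700] m/s")
  if (is.null(breast_center)) breast_center <- numeric(length(breast_semiaxes))
  if (length(breast_center) != length(breast_semiaxes))
    stop("breast_center and breast_semiaxes must have the same length")
  spec <- structure(
    list(breast_semiaxes = breast_semiaxes, breast_center = breast_center,
         c_water = c_water, c_fat = c_fat,
         c_fibroglandular = c_fibroglandular, c_lesion = c_lesion,
         c_skin = c_skin, skin_thickness = skin_thickness,
         blobs = blobs, lesions = lesions, n_blobs = as.integer(n_blobs),
         smoothing_m = smoothing_m, seed = as.integer(seed)),
    class = "phantom_spec"
  )
  for (les in spec$lesions) {
    rel <- (les$center - breast_center) / breast_semiaxes
    if (sqrt(sum(rel^2)) + les$radius / min(breast_semiaxes) > 1)
      stop("lesion lies (partly) outside the breast ellipsoid")
  }
  spec
}

#' Generate a phantom slowness field on a grid
#'
#' Rasterizes the tissue map (water bath, fat ellipsoid, optional skin
#' shell, fibroglandular blobs, lesions; later structures overwrite
#' earlier ones), applies Gaussian smoothing of the specified length, and
#' converts sound speed to slowness. Smoothing is a convex average, so all
#' generated speeds stay within the range of the constituent tissue speeds.
#'
#' @param spec A [phantom_spec()].
#' @param grid A [ust_grid()] with the same dimensionality as the spec
#'   (2D specs give single-slice phantoms).
#' @return A [slowness_field()].
#' @export
generate_phantom <- function(spec, grid) {
  nd <- grid_ndim(grid)
  if (length(spec$breast_semiaxes) != nd)
    stop("phantom spec and grid dimensionality differ")
  ax <- lapply(seq_len(nd), function(a) grid_coords(grid, a))
  coord <- lapply(seq_len(nd), function(a) aperm_broadcast(ax[[a]], a, grid$shape))

  ellip_norm <- function(center, radii) {
    q <- array(0, dim = grid$shape)
    for (a in seq_len(nd)) q <- q + ((coord[[a]] - center[a]) / radii[a])^2
    sqrt(q)
  }

  c_map <- array(spec$c_water, dim = grid$shape)
  breast <- ellip_norm(spec$breast_center, spec$breast_semiaxes)
  c_map[breast <= 1] <- spec$c_fat
  if (spec$skin_thickness > 0) {
    inner <- ellip_norm(spec$breast_center,
                        spec$breast_semiaxes - spec$skin_thickness)
    c_map[breast <= 1 & inner > 1] <- spec$c_skin
  }

  blobs <- spec$blobs
  if (is.null(blobs) && spec$n_blobs > 0) {
    rng <- local_rng(spec$seed)
    blobs <- replicate(spec$n_blobs, simplify = FALSE, {
      u <- rng(nd) * 2 - 1
      list(center = spec$breast_center + 0.5 * u * spec$breast_semiaxes,
           radii = (0.2 + 0.3 * rng(nd)) * spec$breast_semiaxes,
           speed = spec$c_fibroglandular)
    })
  }
  for (b in blobs) c_map[ellip_norm(b$center, b$radii) <= 1] <- b$speed
  for (les in spec$lesions)
    c_map[ellip_norm(les$center, rep(les$radius, nd)) <= 1] <- les$speed

  c_map <- gaussian_smooth(c_map, spec$smoothing_m / grid$h)
  slowness_from_speed(grid, c_map)
}

# Deterministic uniform RNG stream that leaves the global RNG untouched.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    x <- stats::runif(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    x
  }
}

# FFT Gaussian smoothing with a normalized periodic kernel (sigma in voxels).
gaussian_smooth <- function(x, sigma_vox) {
  if (sigma_vox <= 0) return(x)
  shape <- dim(x)
  ker <- array(1, dim = shape)
  for (a in seq_along(shape)) {
    n <- shape[a]
    d <- pmin(0:(n - 1), n - (0:(n - 1)))          # periodic distance
    ka <- exp(-d^2 / (2 * sigma_vox^2))
    ker <- ker * aperm_broadcast(ka, a, shape)
  }
  ker <- ker / sum(ker)
  out <- Re(stats::fft(stats::fft(x) * stats::fft(ker), inverse = TRUE)) / length(x)
  out
}

#' Frequency-domain channel data container
#'
#' Complex receiver measurements per transmit and frequency, with the
#' acquisition geometry attached.
#'
#' @param frequencies Frequencies in Hz.
#' @param matrices List (one per frequency) of complex matrices shaped
#'   `[transmit, receiver]`.
#' @param spec The [ring_array()] used.
#' @param transmits The [transmit_set()] used.
#' @param noise Optional noise descriptor `list(level_db=, seed=)`.
#' @return A `frequency_data` object.
#' @export
frequency_data <- function(frequencies, matrices, spec, transmits, noise = NULL) {
  if (length(frequencies) != length(matrices))
    stop("one data matrix per frequency required")
  n_rec <- spec$n_rows * spec$n_elements_per_row
  for (m in matrices) {
    if (!is.matrix(m) || nrow(m) != length(transmits) || ncol(m) != n_rec)
      stop(sprintf("each data matrix must be %d transmits x %d receivers",
                   length(transmits), n_rec))
    if (any(!is.finite(Mod(m)))) stop("channel data must be finite")
  }
  names(matrices) <- sprintf("f_%d", round(frequencies))
  structure(
    list(frequencies = as.numeric(frequencies), matrices = matrices,
         spec = spec, transmits = transmits, noise = noise),
    class = "frequency_data"
  )
}

#' @export
print.frequency_data <- function(x, ...) {
  cat(sprintf(
    "<frequency_data> %d frequencies (%s kHz), %d transmits x %d receivers%s\n",
    length(x$frequencies),
    paste(round(x$frequencies / 1e3), collapse = ", "),
    nrow(x$matrices[[1]]), ncol(x$matrices[[1]]),
    if (is.null(x$noise)) "" else sprintf(", noise %g dB", x$noise$level_db)
  ))
  invisible(x)
}

#' Synthesize observed channel data from a ground-truth phantom
#'
#' For every frequency and cylindrical-wave transmit, solves the Helmholtz
#' equation in the true medium and samples the field at all array elements:
#' `p = K u`, `u = A^-1 delta_i`. Data are noiseless; apply [add_noise()]
#' afterwards. To avoid committing the inverse crime in experiments, the
#' fields can be simulated on a `sim_refine`-times finer grid than the one
#' the sampling geometry was requested on.
#'
#' @param truth A [slowness_field()] (the ground-truth phantom).
#' @param spec A [ring_array()].
#' @param transmits A [transmit_set()].
#' @param frequencies Frequencies in Hz.
#' @param settings A [born_settings()].
#' @param sim_refine Integer >= 1; 2 simulates on a 2x finer grid.
#' @return A [frequency_data()].
#' @export
simulate_observed_data <- function(truth, spec, transmits, frequencies,
                                   settings = born_settings(), sim_refine = 1L) {
  grid <- truth$grid
  if (sim_refine > 1L) {
    grid <- refine_grid(truth$grid, sim_refine)
    truth <- slowness_field(grid, resample_field(truth, grid))
  }
  K <- sampling_operator(spec, grid)
  mats <- lapply(frequencies, function(f) {
    omega <- 2 * pi * f
    t(vapply(seq_along(transmits), function(i) {
      src <- make_cylindrical_source(K, transmits[i])
      u <- solve_helmholtz(truth, omega, src, settings)
      sample_field(K, u)
    }, complex(K$n_elements)))
  })
  frequency_data(frequencies, mats, spec, transmits)
}

refine_grid <- function(grid, factor) {
  factor <- as.integer(factor)
  ust_grid(grid$shape * factor, grid$spacing / factor,
           origin = grid$origin - grid$spacing * (factor - 1) / (2 * factor))
}

# Multilinear resampling of a real field onto another grid (edge-clamped).
resample_field <- function(field, new_grid) {
  pos <- as.matrix(expand.grid(lapply(seq_len(grid_ndim(new_grid)), function(a)
    grid_coords(new_grid, a))))
  old <- field$grid
  for (a in seq_len(ncol(pos))) {
    lo <- old$origin[a]
    hi <- old$origin[a] + (old$shape[a] - 1) * old$spacing[a]
    pos[, a] <- pmin(pmax(pos[, a], lo), hi - 1e-9 * old$spacing[a])
  }
  st <- point_stencils(pos, old, "linear")
  vals <- rowSums(matrix(field$values[st$idx], nrow = nrow(st$idx)) * st$w)
  array(vals, dim = new_grid$shape)
}

#' Add calibrated complex Gaussian noise to channel data
#'
#' Adds circular complex white Gaussian noise whose total power is
#' `level_db` decibels relative to the mean signal power of each
#' frequency's data matrix (so -20 dB gives a noise-to-signal power ratio
#' of 0.01, i.e. 20 dB SNR), independently per entry and reproducibly per
#' seed.
#'
#' @param data A [frequency_data()].
#' @param level_db Noise level in dB relative to mean signal power
#'   (negative for sub-signal noise).
#' @param seed Integer seed.
#' @return A new [frequency_data()] with noise added and the noise
#'   descriptor recorded.
#' @export
add_noise <- function(data, level_db = -20, seed = 1L) {
  if (level_db >= 0) stop("level_db must be negative (sub-signal noise)")
  rng <- local_rng(seed)
  ratio <- 10^(level_db / 10)
  mats <- lapply(data$matrices, function(m) {
    pw <- mean(Mod(m)^2)
    sd1 <- sqrt(pw * ratio / 2)
    n <- length(m)
    u1 <- rng(n); u2 <- rng(n)
    # Box-Muller from the deterministic uniform stream
    mag <- sqrt(-2 * log(pmax(u1, .Machine$double.xmin)))
    noise <- complex(real = mag * cos(2 * pi * u2),
                     imaginary = mag * sin(2 * pi * u2)) * sd1
    m + noise
  })
  frequency_data(data$frequencies, mats, data$spec, data$transmits,
                 noise = list(level_db = level_db, seed = as.integer(seed)))
}
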