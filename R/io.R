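#' Read and write volumes, channel data and configurations
#'
#' The artifact's on-disk container is R native serialization (`.rds`)
#' holding a schema-checked list: volumes store `values` with `spacing_m`
#' and `origin_m` (and `omega_rad_s` for pressure fields); channel data
#' store one `real`/`imag` matrix pair per frequency plus the acquisition
#' geometry and any noise descriptor. Run configurations are YAML with all
#' defaults echoed. Everything round-trips bit-exactly in 64-bit floats.
#'
#' @param field A [slowness_field()] or `helmholtz_solution`.
#' @param path File path.
#' @return `read_volume()` returns the reconstructed object;
#'   writers return the path invisibly.
#' @name ringfwi_io
NULL

#' @rdname ringfwi_io
#' @export
write_volume <- function(field, path) {
  obj <- list(values = field$values,
              spacing_m = field$grid$spacing,
              origin_m = field$grid$origin)
  if (!is.null(field$omega)) obj$omega_rad_s <- field$omega
  obj$class <- class(field)[1]
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname ringfwi_io
#' @export
read_volume <- function(path) {
  obj <- readRDS(path)
  for (need in c("values", "spacing_m", "origin_m"))
    if (is.null(obj[[need]]))
      stop(sprintf("volume file %s is missing '%s'", path, need))
  grid <- ust_grid(dim(obj$values), obj$spacing_m, obj$origin_m)
  switch(
    if (is.null(obj$class)) "slowness_field" else obj$class,
    slowness_field = slowness_field(grid, obj$values),
    helmholtz_solution = {
      if (is.null(obj$omega_rad_s))
        stop(sprintf("volume file %s is missing 'omega_rad_s'", path))
      helmholtz_solution(grid, obj$omega_rad_s, obj$values, NA_real_, NA_integer_)
    },
    source_field = source_field(grid, obj$values),
    slowness_field(grid, obj$values)
  )
}

#' @rdname ringfwi_io
#' @param data A [frequency_data()].
#' @export
write_frequency_data <- function(data, path) {
  spec <- data$spec
  obj <- list(
    frequencies_hz = data$frequencies,
    geometry = list(radius_m = spec$radius, n_rows = spec$n_rows,
                    n_elements_per_row = spec$n_elements_per_row,
                    row_pitch_m = spec$row_pitch, center_m = spec$center),
    transmit_indices = as.integer(data$transmits),
    noise = data$noise,
    channels = lapply(data$matrices, function(m)
      list(real = Re(m), imag = Im(m)))
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname ringfwi_io
#' @export
read_frequency_data <- function(path) {
  obj <- readRDS(path)
  for (need in c("frequencies_hz", "geometry", "transmit_indices", "channels"))
    if (is.null(obj[[need]]))
      stop(sprintf("data file %s is missing '%s'", path, need))
  geo <- obj$geometry
  for (need in c("radius_m", "n_rows", "n_elements_per_row"))
    if (is.null(geo[[need]]))
      stop(sprintf("data file %s is missing geometry field '%s'", path, need))
  spec <- ring_array(geo$radius_m, geo$n_rows, geo$n_elements_per_row,
                     if (is.null(geo$row_pitch_m)) 2.4e-3 else geo$row_pitch_m,
                     if (is.null(geo$center_m)) c(0, 0, 0) else geo$center_m)
  mats <- lapply(obj$channels, function(ch)
    matrix(complex(real = ch$real, imaginary = ch$imag), nrow = nrow(ch$real)))
  frequency_data(obj$frequencies_hz, mats, spec,
                 transmit_set(spec, obj$transmit_indices), noise = obj$noise)
}

#' Write / read a run configuration as YAML
#'
#' All defaults are echoed so a stored configuration fully reproduces a
#' run.
#'
#' @param config An [fwi_config()].
#' @param path File path.
#' @export
write_config <- function(config, path) {
  st <- config$settings
  obj <- list(
    frequencies_hz = config$frequencies,
    iterations_per_frequency = config$iterations_per_frequency,
    c_start_m_s = config$c_start,
    c_bounds_m_s = config$c_bounds,
    max_dc_first_m_s = config$max_dc_first,
    armijo_c = config$armijo_c,
    backtrack_shrink = config$backtrack_shrink,
    max_backtracks = config$max_backtracks,
    support_radius_m = config$support_radius,
    solver = list(tolerance = st$tolerance,
                  max_iterations = st$max_iterations,
                  pad_width = st$pad_width,
                  absorption = st$absorption,
                  pad_slowness = st$pad_slowness,
                  method = st$method)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  sl <- obj$solver
  settings <- born_settings(
    tolerance = sl$tolerance %||% 1e-4,
    max_iterations = sl$max_iterations %||% 1000L,
    pad_width = sl$pad_width,
    absorption = sl$absorption %||% 1,
    pad_slowness = sl$pad_slowness,
    method = sl$method %||% "born"
  )
  fwi_config(
    frequencies = obj$frequencies_hz,
    iterations_per_frequency = obj$iterations_per_frequency %||% 5L,
    c_start = obj$c_start_m_s %||% 1500,
    c_bounds = unlist(obj$c_bounds_m_s) %||% c(1300, 1700),
    max_dc_first = obj$max_dc_first_m_s %||% 10,
    armijo_c = obj$armijo_c %||% 1e-4,
    backtrack_shrink = obj$backtrack_shrink %||% 0.5,
    max_backtracks = obj$max_backtracks %||% 20L,
    settings = settings,
    support_radius = obj$support_radius_m
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
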