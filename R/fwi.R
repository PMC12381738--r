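#' FWI run configuration
#'
#' Defaults follow the standard multiscale protocol for ring-array
#' sound-speed imaging: ascending frequency schedule (200 to 800 kHz in
#' 50 kHz steps), 5 nonlinear conjugate-gradient iterations at each
#' frequency, a homogeneous 1500 m/s starting model, and each frequency
#' warm-started from the previous frequency's result.
#'
#' @param frequencies Strictly increasing schedule in Hz.
#' @param iterations_per_frequency NCG iterations at each frequency (>= 1).
#' @param c_start Homogeneous starting sound speed, m/s.
#' @param c_bounds Sound-speed clip window (m/s) applied after each update.
#' @param max_dc_first Target size (m/s) of the first model update at each
#'   frequency; sets the initial line-search step.
#' @param armijo_c,backtrack_shrink,max_backtracks Backtracking line-search
#'   parameters (Armijo sufficient-decrease constant, step shrink factor,
#'   trial cap).
#' @param settings A [born_settings()] for the forward/adjoint solves; its
#'   `pad_slowness` defaults to `1/c_start` so the absorbing layer does not
#'   move with the model.
#' @param support_radius Radius (m) of the circular/cylindrical gradient
#'   support mask, or `NULL` for the ring radius (updates are confined to
#'   where the array constrains the model).
#' @return An `fwi_config` object.
#' @export
fwi_config <- function(frequencies = seq(200e3, 800e3, by = 50e3),
                       iterations_per_frequency = 5L,
                       c_start = 1500, c_bounds = c(1300, 1700),
                       max_dc_first = 10,
                       armijo_c = 1e-4, backtrack_shrink = 0.5,
                       max_backtracks = 20L,
                       settings = born_settings(tolerance = 1e-4),
                       support_radius = NULL) {
  if (any(diff(frequencies) <= 0)) stop("frequency schedule must be strictly increasing")
  if (iterations_per_frequency < 1) stop("iterations_per_frequency must be >= 1")
  if (is.null(settings$pad_slowness)) settings$pad_slowness <- 1 / c_start
  structure(
    list(frequencies = as.numeric(frequencies),
         iterations_per_frequency = as.integer(iterations_per_frequency),
         c_start = c_start, c_bounds = c_bounds,
         max_dc_first = max_dc_first, armijo_c = armijo_c,
         backtrack_shrink = backtrack_shrink,
         max_backtracks = as.integer(max_backtracks),
         settings = settings, support_radius = support_radius),
    class = "fwi_config"
  )
}

#' Forward model: fields and array pressures for every transmit
#'
#' Solves the Helmholtz system for each cylindrical-wave transmit source and
#' samples the field at the array: `u_i = A^-1 delta_i`, `p_i = K u_i`.
#'
#' @param s A [slowness_field()].
#' @param omega Angular frequency, rad/s.
#' @param transmits A [transmit_set()].
#' @param K A [sampling_operator()] on the same grid.
#' @param settings A [born_settings()].
#' @return List with `u` (list of complex field arrays) and `p` (complex
#'   matrix `[transmit, receiver]`).
#' @export
forward_model <- function(s, omega, transmits, K, settings = born_settings()) {
  stop_if_grid_mismatch(s$grid, K$grid, "model and sampling operator")
  u <- vector("list", length(transmits))
  p <- matrix(0i, nrow = length(transmits), ncol = K$n_elements)
  for (i in seq_along(transmits)) {
    src <- make_cylindrical_source(K, transmits[i])
    sol <- tryCatch(solve_helmholtz(s, omega, src, settings),
                    error = function(e)
                      stop(sprintf("transmit %d: %s", transmits[i], conditionMessage(e))))
    u[[i]] <- sol$values
    p[i, ] <- sample_field(K, sol)
  }
  list(u = u, p = p)
}

#' Per-transmit complex source scale
#'
#' The amplitude and phase of each physical source is unknown; the
#' least-squares projection `gamma_i = (p_i^H p_obs_i) / (p_i^H p_i)`
#' recovers the complex scale that best matches the simulated to the
#' observed traces. The caller rescales `delta_i`, `u_i`, `p_i` by
#' `gamma_i`.
#'
#' @param p_i Simulated complex traces for one transmit.
#' @param p_obs_i Observed complex traces for the same transmit.
#' @return A complex scalar.
#' @export
estimate_source_scale <- function(p_i, p_obs_i) {
  if (length(p_i) != length(p_obs_i)) stop("trace lengths differ")
  denom <- sum(Conj(p_i) * p_i)
  if (Mod(denom) == 0) stop("simulated traces are identically zero (degenerate transmit)")
  sum(Conj(p_i) * p_obs_i) / denom
}

#' Waveform misfit
#'
#' `E = 1/2 sum_i || p_i - p_obs_i ||^2` over transmits.
#'
#' @param p Simulated complex matrix `[transmit, receiver]` (already source-
#'   scaled).
#' @param p_obs Observed complex matrix of the same shape.
#' @return Nonnegative real scalar.
#' @export
fwi_cost <- function(p, p_obs) {
  if (!all(dim(p) == dim(p_obs))) stop("simulated and observed data shapes differ")
  0.5 * sum(Mod(p - p_obs)^2)
}

#' Adjoint-state gradient of the waveform misfit
#'
#' For each transmit, back-propagates the data residual through the adjoint
#' Helmholtz operator and correlates with the (source-scaled) forward field:
#' per voxel `grad = -sum_i Re{ conj(2 omega^2 s * u_i) * lambda_i }` with
#' `lambda_i = A^-H K^T (p_i - p_obs_i)`. The gradient is zeroed outside the
#' support mask (the absorbing layer lies outside the returned grid by
#' construction).
#'
#' @param s A [slowness_field()].
#' @param omega Angular frequency, rad/s.
#' @param u List of (source-scaled) forward field arrays, one per transmit.
#' @param p Source-scaled simulated traces `[transmit, receiver]`.
#' @param p_obs Observed traces, same shape.
#' @param K A [sampling_operator()].
#' @param settings A [born_settings()].
#' @param mask Optional logical array (grid shape): `FALSE` zeroes the
#'   gradient there.
#' @return Real array of the grid's shape.
#' @export
fwi_gradient <- function(s, omega, u, p, p_obs, K, settings = born_settings(),
                         mask = NULL) {
  grad <- array(0, dim = s$grid$shape)
  for (i in seq_len(nrow(p))) {
    res_i <- p[i, ] - p_obs[i, ]
    lam <- solve_helmholtz_adjoint(s, omega, inject(K, res_i), settings)
    grad <- grad - Re(Conj(2 * omega^2 * s$values * u[[i]]) * lam$values)
  }
  if (!is.null(mask)) grad[!mask] <- 0
  grad
}

# Circular (2D) / cylindrical (3D) support mask inside the given radius.
support_mask <- function(grid, radius, center = c(0, 0)) {
  x <- aperm_broadcast(grid_coords(grid, 1) - center[1], 1, grid$shape)
  y <- aperm_broadcast(grid_coords(grid, 2) - center[2], 2, grid$shape)
  x^2 + y^2 <= radius^2
}

#' One nonlinear conjugate-gradient model update
#'
#' Polak-Ribiere+ search direction with restart to steepest descent on the
#' first iteration (and whenever the direction fails to be a descent
#' direction), then a backtracking Armijo line search on the waveform
#' misfit. The model is clipped to the configured sound-speed bounds after
#' each trial step; a failed line search leaves the model unchanged and
#' flags the state.
#'
#' @param state List carrying `s` (slowness field), `g_prev`, `d_prev`,
#'   `alpha_prev` (or `NULL`s on the first iteration).
#' @param grad Gradient array for the current model.
#' @param cost_fn Function(slowness_field) -> list(cost=, forward=) used by
#'   the line search (forward results at the accepted model are returned
#'   for reuse).
#' @param cost_now Cost at the current model.
#' @param config An [fwi_config()].
#' @return Updated state with fields `s`, `g_prev`, `d_prev`, `alpha_prev`,
#'   `cost`, `forward` (at the new model, or `NULL`), `accepted`.
#' @export
ncg_step <- function(state, grad, cost_fn, cost_now, config) {
  g <- grad
  if (is.null(state$g_prev)) {
    d <- -g
  } else {
    denom <- sum(state$g_prev^2)
    beta <- if (denom > 0) max(0, sum(g * (g - state$g_prev)) / denom) else 0
    d <- -g + beta * state$d_prev
    if (sum(d * g) >= 0) d <- -g      # not a descent direction: restart
  }
  gd <- sum(g * d)
  state$g_prev <- g
  state$d_prev <- d
  state$forward <- NULL
  state$accepted <- FALSE
  if (gd >= 0 || max(abs(d)) == 0) {   # zero gradient: converged fixed point
    state$cost <- cost_now
    return(state)
  }

  s_ref <- mean(state$s$values)
  alpha <- state$alpha_prev
  if (is.null(alpha)) alpha <- config$max_dc_first * s_ref^2 / max(abs(d))
  lo <- 1 / config$c_bounds[2]
  hi <- 1 / config$c_bounds[1]
  for (bt in seq_len(config$max_backtracks)) {
    trial_vals <- pmin(pmax(state$s$values + alpha * d, lo), hi)
    trial <- slowness_field(state$s$grid, trial_vals)
    ev <- cost_fn(trial)
    if (ev$cost <= cost_now + config$armijo_c * alpha * gd) {
      state$s <- trial
      state$cost <- ev$cost
      state$forward <- ev$forward
      state$alpha_prev <- alpha * 2   # optimistic growth for the next step
      state$accepted <- TRUE
      return(state)
    }
    alpha <- alpha * config$backtrack_shrink
  }
  state$cost <- cost_now              # line search failed: keep the model
  state$alpha_prev <- NULL
  state
}

#' Run multi-frequency full waveform inversion
#'
#' Loops the frequency schedule from low to high; at each frequency runs
#' the configured number of NCG iterations of forward modelling,
#' per-transmit complex source estimation, misfit, adjoint-state gradient
#' and line-searched model update. The starting model is homogeneous at
#' `config$c_start`; each frequency warm-starts from the previous one.
#'
#' @param data A [frequency_data()] containing every scheduled frequency.
#' @param config An [fwi_config()].
#' @param grid The inversion [ust_grid()].
#' @param verbose Print per-iteration cost lines.
#' @return An `fwi_result`: `sound_speed` (array, m/s), `slowness`
#'   (the final [slowness_field()]), `history` (data frame of per-iteration
#'   costs), `config`, and `flags` (per-frequency line-search failures).
#' @export
run_fwi <- function(data, config = fwi_config(), grid, verbose = FALSE) {
  if (!all(config$frequencies %in% data$frequencies))
    stop("data do not contain every scheduled frequency")
  K <- sampling_operator(data$spec, grid)
  transmits <- data$transmits
  mask <- NULL
  radius <- config$support_radius
  if (is.null(radius)) radius <- data$spec$radius
  if (is.finite(radius)) mask <- support_mask(grid, radius, data$spec$center)

  state <- list(s = slowness_from_speed(grid, config$c_start),
                g_prev = NULL, d_prev = NULL, alpha_prev = NULL)
  history <- list()
  flags <- character(0)

  for (f in config$frequencies) {
    omega <- 2 * pi * f
    p_obs <- data$matrices[[sprintf("f_%d", round(f))]]
    cost_fn <- function(s_try) {
      fm <- forward_model(s_try, omega, transmits, K, config$settings)
      gam <- vapply(seq_along(transmits), function(i)
        estimate_source_scale(fm$p[i, ], p_obs[i, ]), complex(1))
      fm$p <- fm$p * gam                # gamma recycles down transmit rows
      fm$u <- lapply(seq_along(fm$u), function(i) fm$u[[i]] * gam[i])
      list(cost = fwi_cost(fm$p, p_obs), forward = fm)
    }

    # fresh CG memory at each frequency
    state$g_prev <- NULL; state$d_prev <- NULL; state$alpha_prev <- NULL
    ev <- cost_fn(state$s)
    for (it in seq_len(config$iterations_per_frequency)) {
      grad <- fwi_gradient(state$s, omega, ev$forward$u, ev$forward$p, p_obs,
                           K, config$settings, mask)
      state <- ncg_step(state, grad, cost_fn, ev$cost, config)
      history[[length(history) + 1]] <- data.frame(
        frequency_hz = f, iteration = it, cost = state$cost,
        accepted = state$accepted)
      if (verbose)
        message(sprintf("f = %.0f kHz  it %d  cost %.6e  %s",
                        f / 1e3, it, state$cost,
                        if (state$accepted) "" else "(no step)"))
      if (!state$accepted) {
        if (max(abs(state$g_prev)) > 0)
          flags <- c(flags, sprintf("line search failed at %.0f kHz iteration %d", f / 1e3, it))
        break
      }
      ev <- list(cost = state$cost, forward = state$forward)
    }
  }

  structure(
    list(sound_speed = 1 / state$s$values, slowness = state$s,
         history = do.call(rbind, history), config = config, flags = flags),
    class = "fwi_result"
  )
}

#' @export
print.fwi_result <- function(x, ...) {
  cat(sprintf(
    "<fwi_result> %s volume, %d frequencies, final cost %.4e%s\n",
    paste(dim(x$sound_speed), collapse = "x"),
    length(unique(x$history$frequency_hz)),
    x$history$cost[nrow(x$history)],
    if (length(x$flags)) sprintf(" (%d flags)", length(x$flags)) else ""
  ))
  invisible(x)
}

#' Slicewise 2D full waveform inversion
#'
#' The 2D baseline: assuming no elevational variation in sound speed, each
#' receiver row is treated as sampling a single axial slice. For every row,
#' a 2D inversion is run on the slice grid at that row's height using only
#' that row's receivers per transmit and single-point 2D sources at the
#' transmit azimuths; the 2D reconstructions are stacked into a volume by
#' nearest-row assignment of the grid's z levels.
#'
#' @param data A [frequency_data()] from a multi-row acquisition.
#' @param config An [fwi_config()].
#' @param grid The 3D inversion [ust_grid()] the volume is assembled on.
#' @param verbose Print per-slice progress.
#' @return An `fwi_result` whose `sound_speed` is the stacked volume;
#'   `slices` holds the per-row 2D results.
#' @export
run_slicewise_fwi <- function(data, config = fwi_config(), grid, verbose = FALSE) {
  spec <- data$spec
  if (grid_ndim(grid) != 3) stop("slicewise inversion assembles a 3D volume")
  slice_grid <- ust_grid(grid$shape[1:2], grid$spacing[1:2], grid$origin[1:2])
  ring2d <- ring_array(spec$radius, n_rows = 1L,
                       n_elements_per_row = spec$n_elements_per_row,
                       center = spec$center[1:2])
  nel <- spec$n_elements_per_row
  slices <- vector("list", spec$n_rows)
  flags <- character(0)
  history <- list()

  for (r in seq_len(spec$n_rows)) {
    cols <- (r - 1) * nel + seq_len(nel)
    sub <- lapply(data$matrices, function(m) m[, cols, drop = FALSE])
    data2d <- frequency_data(data$frequencies, sub, ring2d, data$transmits)
    res <- tryCatch(
      run_fwi(data2d, config, slice_grid, verbose = FALSE),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      flags <- c(flags, sprintf("slice %d failed: %s", r, conditionMessage(res)))
      slices[[r]] <- array(config$c_start, dim = slice_grid$shape)
    } else {
      slices[[r]] <- res$sound_speed
      h <- res$history; h$row <- r
      history[[length(history) + 1]] <- h
      flags <- c(flags, res$flags)
    }
    if (verbose) message(sprintf("slice %d/%d done", r, spec$n_rows))
  }

  z0 <- if (length(spec$center) >= 3) spec$center[3] else 0
  heights <- z0 + (seq_len(spec$n_rows) - (spec$n_rows + 1) / 2) * spec$row_pitch
  zc <- grid_coords(grid, 3)
  vol <- array(config$c_start, dim = grid$shape)
  for (k in seq_along(zc)) {
    r <- which.min(abs(heights - zc[k]))
    vol[, , k] <- slices[[r]]
  }

  structure(
    list(sound_speed = vol, slices = slices,
         history = if (length(history)) do.call(rbind, history) else NULL,
         config = config, flags = flags),
    class = "fwi_result"
  )
}
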