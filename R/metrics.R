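#' Evaluate a reconstruction against ground truth
#'
#' Root-mean-square error (m/s) and Pearson's correlation coefficient
#' between reconstructed and true sound-speed volumes over an optional
#' mask. The default region is the whole inversion volume (the absorbing
#' layer is internal to the solver and never part of the volume); pass a
#' breast mask to restrict to tissue.
#'
#' @param recon Reconstructed sound-speed array (m/s), or an `fwi_result`.
#' @param truth Ground-truth sound-speed array (m/s), or a
#'   [slowness_field()].
#' @param mask Optional logical array of the same shape; must select at
#'   least two voxels.
#' @return An `evaluation_report`: `rmse` (m/s), `pcc`, `n_voxels`,
#'   `mask_used`.
#' @examples
#' a <- array(1500 + rnorm(64), c(8, 8))
#' evaluate_reconstruction(a + 10, a)   # rmse 10, pcc 1
#' @export
evaluate_reconstruction <- function(recon, truth, mask = NULL) {
  if (inherits(recon, "fwi_result")) recon <- recon$sound_speed
  if (inherits(truth, "slowness_field")) truth <- 1 / truth$values
  if (!all(dim(recon) == dim(truth)))
    stop("reconstruction and truth shapes differ")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(truth))
  if (sum(mask) < 2) stop("mask must select at least two voxels")
  a <- recon[mask]; b <- truth[mask]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("PCC is undefined for a constant volume over the mask")
  structure(
    list(rmse = sqrt(mean((a - b)^2)),
         pcc = stats::cor(a, b),
         n_voxels = sum(mask),
         mask_used = !all(mask)),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> RMSE %.2f m/s, PCC %.4f (%d voxels%s)\n",
              x$rmse, x$pcc, x$n_voxels,
              if (x$mask_used) ", masked" else ""))
  invisible(x)
}

#' Orthographic slice plot of a sound-speed volume
#'
#' Displays the three central orthogonal slices (or the single slice for a
#' 2D field) in the conventional 1400-1600 m/s grayscale window.
#'
#' @param volume Sound-speed array (m/s), `fwi_result`, or
#'   [slowness_field()].
#' @param zlim Display window, m/s.
#' @param ... Passed to [graphics::image()].
#' @export
plot_sound_speed <- function(volume, zlim = c(1400, 1600), ...) {
  if (inherits(volume, "fwi_result")) volume <- volume$sound_speed
  if (inherits(volume, "slowness_field")) volume <- 1 / volume$values
  gray <- grDevices::gray.colors(128, 0, 1)
  clamp <- function(m) pmin(pmax(m, zlim[1]), zlim[2])
  if (length(dim(volume)) == 2) {
    graphics::image(clamp(volume), col = gray, zlim = zlim, asp = 1, ...)
    return(invisible(NULL))
  }
  op <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  mids <- ceiling(dim(volume) / 2)
  graphics::image(clamp(volume[, , mids[3]]), col = gray, zlim = zlim,
                  asp = 1, main = "axial", axes = FALSE)
  graphics::image(clamp(volume[, mids[2], ]), col = gray, zlim = zlim,
                  asp = 1, main = "coronal", axes = FALSE)
  graphics::image(clamp(volume[mids[1], , ]), col = gray, zlim = zlim,
                  asp = 1, main = "sagittal", axes = FALSE)
  invisible(NULL)
}
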