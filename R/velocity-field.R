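#' Time-resolved three-component velocity field
#'
#' Container for reconstructed 4D flow CMR velocities: three X x Y x Z x T
#' arrays (one per velocity component, m/s) plus acquisition metadata.
#' World coordinates are `0-based voxel index * spacing` (mm).
#'
#' @param vx,vy,vz 4D numeric arrays (X x Y x Z x T), velocities in m/s.
#' @param spacing numeric length-3, voxel spacing in mm.
#' @param dt_ms temporal resolution in ms.
#' @param venc velocity encoding sensitivity in m/s; stored velocities of a
#'   freshly reconstructed field lie in `[-venc, venc)`.
#' @param magnitude optional X x Y x Z magnitude image.
#'
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(vx, vy, vz, spacing, dt_ms, venc, magnitude = NULL) {
  stopifnot(length(dim(vx)) == 4, identical(dim(vx), dim(vy)),
            identical(dim(vx), dim(vz)))
  if (any(spacing <= 0)) stop("voxel spacing must be positive")
  if (venc <= 0) stop("venc must be positive")
  if (dim(vx)[4] < 2) stop("a velocity field needs at least 2 cardiac phases")
  structure(
    list(vx = vx, vy = vy, vz = vz,
         spacing = as.numeric(spacing), dt_ms = as.numeric(dt_ms),
         venc = as.numeric(venc), magnitude = magnitude),
    class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$vx)
  cat(sprintf("<velocity_field> %d x %d x %d voxels, %d phases\n", d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing %.2f x %.2f x %.2f mm, dt %.1f ms, venc %.2f m/s\n",
              x$spacing[1], x$spacing[2], x$spacing[3], x$dt_ms, x$venc))
  invisible(x)
}

#' Sampling times of the cardiac phases
#' @param field A `velocity_field`.
#' @return Numeric vector of phase times in seconds (phase 1 at t = 0).
#' @export
phase_times <- function(field) {
  (seq_len(dim(field$vx)[4]) - 1) * field$dt_ms / 1000
}

#' Binary lumen mask
#'
#' @param mask 3D logical array (static over the cardiac cycle).
#' @param spacing voxel spacing in mm (length 3).
#' @return An object of class `lumen_mask`.
#' @export
lumen_mask <- function(mask, spacing) {
  stopifnot(length(dim(mask)) == 3, is.logical(mask))
  if (!any(mask)) stop("lumen mask is empty")
  structure(list(mask = mask, spacing = as.numeric(spacing)), class = "lumen_mask")
}

#' @export
print.lumen_mask <- function(x, ...) {
  cat(sprintf("<lumen_mask> %s voxels set of %s, spacing %.2f x %.2f x %.2f mm\n",
              sum(x$mask), length(x$mask), x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}
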