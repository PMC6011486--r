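#' Correct velocity phase wraps
#'
#' Velocities beyond the encoding sensitivity alias by multiples of
#' `2 * venc`. This temporal unwrapping anchors each voxel at its stored
#' phase-1 value and, walking forward in time, adds the multiple of
#' `2 * venc` that minimises the jump against the previous phase. On
#' wrap-free data it is the identity, and it is idempotent.
#'
#' @param field A [velocity_field()].
#' @return A [velocity_field()] with unwrapped components.
#' @export
unwrap_velocity <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  if (field$venc <= 0) stop("venc must be positive")
  two_venc <- 2 * field$venc
  unwrap1 <- function(v) {
    d <- dim(v)
    n <- prod(d[1:3])
    prev <- v[seq_len(n)]
    for (k in 2:d[4]) {
      idx <- (k - 1) * n + seq_len(n)
      cur <- v[idx] + two_venc * round((prev - v[idx]) / two_venc)
      v[idx] <- cur
      prev <- cur
    }
    v
  }
  velocity_field(unwrap1(field$vx), unwrap1(field$vy), unwrap1(field$vz),
                 field$spacing, field$dt_ms, field$venc, field$magnitude)
}

#' Mask of static tissue around the lumen
#'
#' Convenience helper: the complement of the lumen dilated by `margin_vox`
#' voxels, i.e. everything safely outside the vessel. Used as the fitting
#' region for eddy-current correction.
#'
#' @param lumen A [lumen_mask()].
#' @param margin_vox dilation margin in voxels.
#' @return A 3D logical array.
#' @export
static_tissue_mask <- function(lumen, margin_vox = 2L) {
  m <- lumen$mask
  for (i in seq_len(margin_vox)) m <- dilate6(m)
  !m
}

#' Correct eddy-current velocity offsets
#'
#' Residual eddy currents leave a slowly varying velocity offset across the
#' volume. A first-order spatial polynomial (offset plus linear gradients in
#' x, y, z) is fitted per component to the temporal-mean velocity over
#' static-tissue voxels and subtracted from every phase. After correction
#' the static temporal-mean velocity is zero-mean to least-squares
#' tolerance.
#'
#' @param field A [velocity_field()].
#' @param static_mask 3D logical array of static-tissue voxels (see
#'   [static_tissue_mask()]); must be disjoint from the lumen.
#' @return A corrected [velocity_field()] with the fitted coefficients
#'   attached as attribute `"eddy_fit"` (per component: `c(b0, bx, by, bz)`,
#'   x/y/z in mm).
#' @export
correct_eddy_currents <- function(field, static_mask) {
  stopifnot(inherits(field, "velocity_field"),
            identical(dim(static_mask), dim(field$vx)[1:3]))
  n_static <- sum(static_mask)
  if (n_static < 8)
    stop("static mask too small to determine the 4 polynomial coefficients")
  d <- dim(field$vx)
  n <- prod(d[1:3])
  sp <- field$spacing
  i0 <- seq_len(n) - 1L
  wx <- (i0 %% d[1]) * sp[1]
  wy <- ((i0 %/% d[1]) %% d[2]) * sp[2]
  wz <- (i0 %/% (d[1] * d[2])) * sp[3]
  X <- cbind(1, wx, wy, wz)
  sel <- which(static_mask)
  fits <- list()
  correct1 <- function(v, name) {
    tm <- rowMeans(matrix(v, n, d[4]))
    beta <- stats::lm.fit(X[sel, , drop = FALSE], tm[sel])$coefficients
    fits[[name]] <<- unname(beta)
    off <- as.numeric(X %*% beta)
    v - array(off, d)
  }
  vx <- correct1(field$vx, "vx")
  vy <- correct1(field$vy, "vy")
  vz <- correct1(field$vz, "vz")
  out <- velocity_field(vx, vy, vz, field$spacing, field$dt_ms, field$venc,
                        field$magnitude)
  attr(out, "eddy_fit") <- fits
  out
}

#' Segment the aortic lumen
#'
#' Reproducible stand-in for the semi-automatic segmentation of clinical
#' software: threshold the temporal-maximum speed at a fraction of its
#' global maximum, keep the largest connected component (or, when a seed
#' point is given, the component containing it), and close small gaps
#' morphologically.
#'
#' @param field A preprocessed [velocity_field()].
#' @param threshold_fraction speed threshold as a fraction of the global
#'   temporal-maximum speed (default 0.2).
#' @param seed_mm optional world-coordinate point inside the vessel; selects
#'   that component instead of the largest.
#' @param closing_iter rounds of morphological closing (default 1).
#' @return A [lumen_mask()].
#' @export
segment_lumen <- function(field, threshold_fraction = 0.2, seed_mm = NULL,
                          closing_iter = 1L) {
  stopifnot(inherits(field, "velocity_field"))
  d <- dim(field$vx)
  n <- prod(d[1:3])
  speed_max <- rep(0, n)
  for (k in seq_len(d[4])) {
    idx <- (k - 1) * n + seq_len(n)
    sp_k <- sqrt(field$vx[idx]^2 + field$vy[idx]^2 + field$vz[idx]^2)
    speed_max <- pmax(speed_max, sp_k)
  }
  thr <- threshold_fraction * max(speed_max)
  mask <- array(speed_max > thr, d[1:3])
  if (!any(mask))
    stop(sprintf("empty segmentation at threshold fraction %.2f; lower the threshold", threshold_fraction))
  if (is.null(seed_mm)) {
    mask <- largest_component6(mask)
  } else {
    i <- round(seed_mm / field$spacing)
    if (any(i < 0) || any(i >= d[1:3])) stop("seed point outside the volume")
    lin <- 1L + i[1] + d[1] * (i[2] + d[2] * i[3])
    if (!mask[lin]) stop("seed point is not inside the thresholded region")
    mask <- flood_fill6(mask, as.integer(lin))
  }
  if (closing_iter > 0) mask <- close6(mask, closing_iter)
  lumen_mask(mask, field$spacing)
}
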