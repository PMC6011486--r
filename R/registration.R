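# Multi-scale phase-difference registration.
#
# Dense displacement between two frames is estimated from the local phase
# differences of oriented band-pass quadrature (log-Gabor) filter
# responses: the phase shift of each oriented response is proportional to
# the displacement along that orientation, independent of local image
# intensity. Per pixel, the displacements suggested by the orientations
# are combined by magnitude-weighted least squares, smoothed by normalized
# convolution, and accumulated coarse-to-fine over a fixed schedule of
# filter wavelengths with warp-and-re-estimate iterations at each scale.
# This is a fixed-schedule simplification of Morphon-style phase
# registration (no certainty propagation across scales).

# Oriented log-Gabor quadrature filters in the frequency domain.
# Returns a list of complex transfer matrices, one per orientation.
quadrature_bank <- function(n_rows, n_cols, wavelength_px,
                            orientations = c(0, pi / 4, pi / 2, 3 * pi / 4)) {
  fx <- (seq_len(n_rows) - 1) / n_rows
  fx[fx >= 0.5] <- fx[fx >= 0.5] - 1
  fy <- (seq_len(n_cols) - 1) / n_cols
  fy[fy >= 0.5] <- fy[fy >= 0.5] - 1
  FX <- matrix(fx, n_rows, n_cols)
  FY <- matrix(fy, n_rows, n_cols, byrow = TRUE)
  f <- sqrt(FX^2 + FY^2)
  f0 <- 1 / wavelength_px
  radial <- exp(-(log(pmax(f, 1e-12) / f0))^2 / (2 * log(0.65)^2))
  radial[1, 1] <- 0                              # kill DC
  ang <- atan2(FY, FX)
  lapply(orientations, function(phi) {
    dphi <- atan2(sin(ang - phi), cos(ang - phi))
    spread <- cos(pmin(abs(dphi), pi / 2))^2     # angular tuning
    half <- abs(dphi) < pi / 2                   # one half-plane: quadrature
    radial * spread * half
  })
}

quadrature_responses <- function(img, bank) {
  FI <- stats::fft(img)
  lapply(bank, function(tf) stats::fft(FI * tf, inverse = TRUE) / length(img))
}

# Normalized-convolution Gaussian smoothing of a field with certainty c.
smooth_certain <- function(field, certainty, sd_px) {
  num <- gauss_blur2(field * certainty, sd_px)
  den <- gauss_blur2(certainty, sd_px)
  out <- num / pmax(den, 1e-12)
  out[den < 1e-12] <- 0
  out
}

# Single-scale displacement update between fixed and (already warped)
# moving frames. Returns list(ux, uy, certainty).
phase_flow_step <- function(fixed, moving, bank, orientations, wavelength_px) {
  qf <- quadrature_responses(fixed, bank)
  qm <- quadrature_responses(moving, bank)
  k0 <- 2 * pi / wavelength_px
  m11 <- 0; m12 <- 0; m22 <- 0; b1 <- 0; b2 <- 0
  for (i in seq_along(bank)) {
    p <- qf[[i]] * Conj(qm[[i]])
    c_i <- Mod(p)
    dphi <- Arg(p)
    d_i <- dphi / k0                            # displacement along n_i (px)
    nx <- cos(orientations[i]); ny <- sin(orientations[i])
    m11 <- m11 + c_i * nx * nx
    m12 <- m12 + c_i * nx * ny
    m22 <- m22 + c_i * ny * ny
    b1 <- b1 + c_i * d_i * nx
    b2 <- b2 + c_i * d_i * ny
  }
  det <- m11 * m22 - m12^2
  eps <- 1e-6 * max(det)
  det <- det + eps
  ux <- (m22 * b1 - m12 * b2) / det
  uy <- (m11 * b2 - m12 * b1) / det
  cert <- m11 + m22                              # total certainty (trace)
  list(ux = ux, uy = uy, certainty = cert)
}

# Sinc (Fourier zero-padding) upsampling. The CINE vessel edge is only
# marginally sampled, so local interpolants resample it with errors that a
# phase registration reads as spurious boundary motion; sampling a sinc-
# upsampled grid instead keeps the warp faithful to the band-limited image.
fft_upsample <- function(img, factor = 4L) {
  d <- dim(img)
  F <- stats::fft(img)
  N1 <- d[1] * factor; N2 <- d[2] * factor
  G <- matrix(0 + 0i, N1, N2)
  h1 <- d[1] %/% 2; h2 <- d[2] %/% 2
  G[c(1:h1, (N1 - h1 + 1):N1), c(1:h2, (N2 - h2 + 1):N2)] <-
    F[c(1:h1, (d[1] - h1 + 1):d[1]), c(1:h2, (d[2] - h2 + 1):d[2])]
  Re(stats::fft(G, inverse = TRUE)) / length(img)
}

# Warp an image by a displacement field: out(x) = img(x + u(x)).
# Sampling happens on a sinc-upsampled grid (see fft_upsample); a
# pre-upsampled image can be passed to avoid recomputing it per iteration.
warp_image <- function(img, ux, uy, upsampled = NULL, factor = 4L) {
  d <- dim(img)
  if (is.null(upsampled)) upsampled <- fft_upsample(img, factor)
  gx <- matrix(seq_len(d[1]) - 1, d[1], d[2])
  gy <- matrix(seq_len(d[2]) - 1, d[1], d[2], byrow = TRUE)
  pts <- cbind(as.vector(gx + ux), as.vector(gy + uy)) * factor
  du <- dim(upsampled)
  pts[, 1] <- pmin(pmax(pts[, 1], 0), du[1] - 1)
  pts[, 2] <- pmin(pmax(pts[, 2], 0), du[2] - 1)
  matrix(interp2(upsampled, pts), d[1], d[2])
}

#' Dense displacement between two frames by phase-based registration
#'
#' Estimates the material displacement field `u` such that points at `x` in
#' `fixed` move to `x + u(x)` in `moving`, from local phase differences of
#' oriented band-pass quadrature responses, coarse-to-fine with a fixed
#' iteration schedule. Deterministic.
#'
#' @param fixed,moving 2D numeric matrices (same size).
#' @param wavelengths_px filter wavelengths per scale, coarse to fine.
#' @param iterations warp-and-re-estimate iterations per scale.
#' @param smooth_sd_px Gaussian sd of the displacement regulariser (px).
#' @return List with `ux`, `uy` (displacement in pixels, matrices).
#' @export
register_phase <- function(fixed, moving, wavelengths_px = c(16, 8, 4),
                           iterations = 3, smooth_sd_px = 2.5) {
  stopifnot(identical(dim(fixed), dim(moving)))
  d <- dim(fixed)
  ux <- matrix(0, d[1], d[2]); uy <- matrix(0, d[1], d[2])
  moving_up <- fft_upsample(moving)
  for (wl in wavelengths_px) {
    bank <- quadrature_bank(d[1], d[2], wl)
    orient <- c(0, pi / 4, pi / 2, 3 * pi / 4)
    for (it in seq_len(iterations)) {
      warped <- warp_image(moving, ux, uy, upsampled = moving_up)
      # phase difference fixed vs warped gives the *residual* displacement
      upd <- phase_flow_step(fixed, warped, bank, orient, wl)
      dux <- smooth_certain(upd$ux, upd$certainty, smooth_sd_px)
      duy <- smooth_certain(upd$uy, upd$certainty, smooth_sd_px)
      # cap the update at half a wavelength (phase is only defined there)
      cap <- wl / 2
      dux <- pmin(pmax(dux, -cap), cap)
      duy <- pmin(pmax(duy, -cap), cap)
      ux <- ux + dux
      uy <- uy + duy
    }
  }
  list(ux = ux, uy = uy)
}
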