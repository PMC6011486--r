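#' 2D CINE image series
#'
#' A single-slice, multi-phase intensity series as produced by retrospective
#' ECG-gated CINE imaging of an aortic cross-section.
#'
#' @param frames 3D numeric array (X x Y x n_phases).
#' @param spacing_mm in-plane pixel spacing (scalar, isotropic).
#' @param dt_ms frame interval in ms.
#' @return An object of class `cine_series`.
#' @export
cine_series <- function(frames, spacing_mm, dt_ms) {
  stopifnot(length(dim(frames)) == 3)
  if (dim(frames)[3] < 2) stop("a CINE series needs at least 2 phases")
  if (spacing_mm <= 0) stop("pixel spacing must be positive")
  structure(list(frames = frames, spacing_mm = spacing_mm, dt_ms = dt_ms),
            class = "cine_series")
}

#' @export
print.cine_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cine_series> %d x %d px, %d phases, %.2f mm/px, %.0f ms/frame\n",
              d[1], d[2], d[3], x$spacing_mm, x$dt_ms))
  invisible(x)
}

#' Default aortic pulsation waveform over the cardiac phases
#'
#' Fraction of the full diameter excursion at each phase: zero in diastole
#' with a raised-cosine systolic bump (rise over `n_up` frames from
#' `onset`, fall over `n_down`).
#'
#' @param n_phases number of frames.
#' @param onset first frame (1-based) of the upstroke.
#' @param n_up,n_down frames of the rise and fall.
#' @return Numeric vector in `[0, 1]`, zero at the end-diastolic frame.
#' @export
pulsation_waveform <- function(n_phases = 25, onset = 3, n_up = 6, n_down = 9) {
  k <- seq_len(n_phases) - onset
  w <- numeric(n_phases)
  up <- k > 0 & k <= n_up
  dn <- k > n_up & k < n_up + n_down
  w[up] <- (1 - cos(pi * k[up] / n_up)) / 2
  w[dn] <- (1 + cos(pi * (k[dn] - n_up) / n_down)) / 2
  w
}

#' Specification of a 2D CINE phantom
#'
#' A pulsating bright disk (vessel lumen) on a darker background, rendered
#' with sub-pixel anti-aliasing, optional Gaussian blur and noise. Defaults
#' emulate a retrospectively gated FLASH CINE of the aorta: 25 phases,
#' 1.8 mm pixels, ~40 ms frames.
#'
#' @param dd_mm end-diastolic diameter (mm).
#' @param delta_d_mm systolic diameter excursion (mm); the frame-k diameter
#'   is `dd_mm + delta_d_mm * w_k` with `w_k` in `[0, 1]`.
#' @param waveform pulsation fractions per phase (see
#'   [pulsation_waveform()]); length defines `n_phases` when they disagree.
#' @param spacing_mm pixel spacing.
#' @param n_phases number of frames.
#' @param size_px image side in pixels.
#' @param vessel_intensity,background_intensity image intensities.
#' @param blur_sd_px Gaussian blur sd in pixels (0 = none).
#' @param noise_sd additive Gaussian intensity noise sd.
#' @param center_px optional disk centre (0-based pixel coords); default the
#'   image centre.
#' @param seed RNG seed for the noise.
#' @return An object of class `cine_phantom_spec`.
#' @export
cine_phantom_spec <- function(dd_mm = 24, delta_d_mm = 2, waveform = NULL,
                              spacing_mm = 1.8, n_phases = 25, size_px = 64,
                              vessel_intensity = 1, background_intensity = 0.15,
                              blur_sd_px = 0.5, noise_sd = 0.02,
                              center_px = NULL, seed = NULL) {
  if (delta_d_mm < 0) stop("delta_d_mm must be non-negative")
  if (dd_mm <= delta_d_mm) stop("end-diastolic diameter must exceed the excursion")
  if (n_phases < 2) stop("n_phases must be at least 2")
  if (is.null(waveform)) waveform <- pulsation_waveform(n_phases)
  if (length(waveform) != n_phases) n_phases <- length(waveform)
  if (any(waveform < 0 | waveform > 1)) stop("waveform fractions must lie in [0, 1]")
  if (is.null(center_px)) center_px <- c((size_px - 1) / 2, (size_px - 1) / 2)
  structure(as.list(environment()), class = "cine_phantom_spec")
}

# separable Gaussian blur with a small discrete kernel
gauss_blur2 <- function(img, sd_px) {
  if (sd_px <= 0) return(img)
  r <- max(1L, ceiling(3 * sd_px))
  k <- stats::dnorm(-r:r, sd = sd_px)
  k <- k / sum(k)
  pad <- function(m, n) m[c(rep(1, n), seq_len(nrow(m)), rep(nrow(m), n)), , drop = FALSE]
  conv_rows <- function(m) {
    mp <- pad(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * mp[j:(j + nrow(m) - 1), , drop = FALSE]
    out
  }
  t(conv_rows(t(conv_rows(img))))
}

#' Generate a 2D CINE phantom with its true diameter curve
#'
#' Each frame depicts a disk of diameter `dd_mm + delta_d_mm * w_k`. The
#' disk edge is rendered with analytic sub-pixel coverage (clamped signed
#' distance), then blurred and corrupted with noise as requested.
#'
#' @param spec A [cine_phantom_spec()].
#' @return A list with `cine` (a [cine_series()]) and `truth` (a
#'   [diameter_curve()] listing the exact per-frame diameters).
#' @export
make_cine_phantom <- function(spec) {
  stopifnot(inherits(spec, "cine_phantom_spec"))
  n <- spec$size_px
  sp <- spec$spacing_mm
  r_max_px <- (spec$dd_mm + spec$delta_d_mm) / 2 / sp
  ctr <- spec$center_px
  if (ctr[1] - r_max_px < 1 || ctr[2] - r_max_px < 1 ||
      ctr[1] + r_max_px > n - 2 || ctr[2] + r_max_px > n - 2)
    stop("disk exceeds the image bounds; enlarge size_px or shrink the diameter")
  xs <- (seq_len(n) - 1)
  rho <- sqrt(outer((xs - ctr[1])^2, (xs - ctr[2])^2, `+`))
  d_k <- spec$dd_mm + spec$delta_d_mm * spec$waveform
  frames <- array(0, c(n, n, spec$n_phases))
  bg <- spec$background_intensity; vi <- spec$vessel_intensity
  mk <- function(r_px) {
    cov <- pmin(pmax(r_px - rho + 0.5, 0), 1)     # sub-pixel edge coverage
    img <- bg + (vi - bg) * cov
    gauss_blur2(img, spec$blur_sd_px)
  }
  for (k in seq_len(spec$n_phases)) frames[, , k] <- mk(d_k[k] / 2 / sp)
  if (spec$noise_sd > 0) {
    frames <- with_seed(spec$seed,
      frames + array(stats::rnorm(length(frames), 0, spec$noise_sd), dim(frames)))
  }
  truth <- diameter_curve(d_k, end_diastolic_frame = which.min(d_k))
  list(cine = cine_series(frames, sp, 1000 / spec$n_phases),
       truth = truth, spec = spec)
}
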