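# Digital 4D flow phantom: a candy-cane tube carrying a systolic velocity
# pulse that propagates along the centerline at a known pulse wave velocity.
# Everything downstream (unwrapping, eddy correction, segmentation,
# centerline, planes, waveforms, PWV) can be validated against its truth.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Systolic pulse template
#'
#' Raised-cosine upstroke and downstroke over a flat (zero) diastolic
#' baseline: zero before `onset_s`, rising to `peak` over `upstroke_s`,
#' returning to baseline over `downstroke_s`. The shape has a well-defined
#' foot, half-peak crossing and peak, so all three wave-arrival detectors
#' are exercised by the same phantom.
#'
#' @param t times in seconds (vectorised).
#' @param onset_s pulse onset (the "foot") in seconds.
#' @param upstroke_s upstroke duration in seconds.
#' @param downstroke_s downstroke duration in seconds.
#' @param peak peak centerline velocity in m/s.
#' @return Velocities in m/s at `t`.
#' @export
pulse_waveform <- function(t, onset_s = 0.06, upstroke_s = 0.08,
                           downstroke_s = 0.12, peak = 1.0) {
  v <- numeric(length(t))
  up <- t > onset_s & t <= onset_s + upstroke_s
  dn <- t > onset_s + upstroke_s & t < onset_s + upstroke_s + downstroke_s
  v[up] <- peak * (1 - cos(pi * (t[up] - onset_s) / upstroke_s)) / 2
  v[dn] <- peak * (1 + cos(pi * (t[dn] - onset_s - upstroke_s) / downstroke_s)) / 2
  v
}

#' Specification of a 4D flow phantom
#'
#' Defaults emulate the acquisition the pipeline targets: 2.5 x 2.1 x 2.5 mm
#' voxels, 20 ms temporal resolution, venc 1.5 m/s, and a thoracic aorta of
#' roughly 30 cm centerline length (ascending limb + semicircular arch +
#' descending limb).
#'
#' @param ascending_mm,arch_radius_mm,descending_mm candy-cane geometry (mm);
#'   total centerline length is `ascending + pi * arch_radius + descending`.
#' @param lumen_radius_mm lumen radius (mm); must be at least twice the
#'   largest voxel spacing so the lumen is resolvable.
#' @param true_pwv pulse wave velocity of the phantom in m/s.
#' @param onset_s,upstroke_s,downstroke_s,peak_velocity waveform shape; see
#'   [pulse_waveform()].
#' @param profile velocity profile across the lumen: `"plug"` (uniform) or
#'   `"parabolic"` (Poiseuille, zero at the wall, `peak_velocity` on axis).
#' @param spacing voxel spacing mm (length 3).
#' @param dt_ms temporal resolution ms.
#' @param n_phases number of reconstructed cardiac phases.
#' @param venc velocity sensitivity m/s.
#' @param noise_sd Gaussian velocity noise sd (m/s), added per component.
#' @param eddy list of three length-4 vectors `c(b0, bx, by, bz)` — a
#'   first-order spatial polynomial offset (m/s, with x,y,z in mm) added to
#'   each component to emulate residual eddy-current phase errors; `NULL`
#'   for none.
#' @param wrap_enabled if `TRUE`, stored velocities are aliased into
#'   `[-venc, venc)` as a phase-contrast reconstruction would.
#' @param seed RNG seed for the noise; fixed seed gives bit-identical output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(ascending_mm = 60, arch_radius_mm = 35,
                         descending_mm = 130, lumen_radius_mm = 12,
                         true_pwv = 5, onset_s = 0.06, upstroke_s = 0.08,
                         downstroke_s = 0.12, peak_velocity = 1.0,
                         profile = c("plug", "parabolic"),
                         spacing = c(2.5, 2.1, 2.5), dt_ms = 20,
                         n_phases = 20, venc = 1.5, noise_sd = 0,
                         eddy = NULL, wrap_enabled = FALSE, seed = NULL) {
  profile <- match.arg(profile)
  if (true_pwv <= 0) stop("true_pwv must be positive")
  if (n_phases < 2) stop("n_phases must be at least 2")
  if (venc <= 0) stop("venc must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (lumen_radius_mm < 2 * max(spacing))
    stop(sprintf(paste("lumen radius %.1f mm is unresolvable at voxel spacing",
                       "%.1f mm (need radius >= 2 x max spacing)"),
                 lumen_radius_mm, max(spacing)))
  structure(as.list(environment()), class = "phantom_spec")
}

#' Generate a 4D flow phantom with ground truth
#'
#' Builds the velocity field of a pressure pulse travelling along a
#' candy-cane tube: the through-lumen velocity at centerline arc length `s`
#' and time `t` is `waveform(t - s / true_pwv)` scaled by the radial profile
#' and directed along the local tangent. Outside the lumen the velocity is
#' zero apart from the requested artifacts (noise, eddy offsets, wrapping).
#'
#' @param spec A [phantom_spec()].
#' @return A list with `field` (a [velocity_field()]), `centerline` (the true
#'   [centerline()]), `lumen` (the true [lumen_mask()]), and `spec`.
#' @export
make_flow_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- candy_cane(spec$ascending_mm, spec$arch_radius_mm, spec$descending_mm)
  r <- spec$lumen_radius_mm
  margin <- 8
  # world-extent bounding box of the tube plus margin
  xr <- c(-r - margin, 2 * geom$Ra + r + margin)
  yr <- c(-r - margin, r + margin)
  zr <- c(min(0, geom$La - geom$Ld) - r - margin, geom$La + geom$Ra + r + margin)
  sp <- spec$spacing
  nx <- ceiling(diff(xr) / sp[1]) + 1
  ny <- ceiling(diff(yr) / sp[2]) + 1
  nz <- ceiling(diff(zr) / sp[3]) + 1
  # voxel (0,0,0) sits at world origin_shift; keep geometry origin at
  # world position -xr[1], -yr[1], -zr[1] so all voxel coords are >= 0
  geom <- candy_cane(spec$ascending_mm, spec$arch_radius_mm, spec$descending_mm,
                     origin = c(-xr[1], -yr[1], -zr[1]))

  ix <- (seq_len(nx) - 1) * sp[1]
  iy <- (seq_len(ny) - 1) * sp[2]
  iz <- (seq_len(nz) - 1) * sp[3]
  pts <- as.matrix(expand.grid(x = ix, y = iy, z = iz))
  cl <- candy_cane_closest(geom, pts)
  inside <- cl$dist <= r
  prof <- switch(spec$profile,
                 plug = as.numeric(inside),
                 parabolic = ifelse(inside, 1 - (cl$dist / r)^2, 0))
  delay <- cl$s / 1000 / spec$true_pwv   # s in mm -> transit delay in s

  n_t <- spec$n_phases
  t_k <- (seq_len(n_t) - 1) * spec$dt_ms / 1000
  pulse_end <- spec$onset_s + spec$upstroke_s + spec$downstroke_s
  if (max(t_k) < pulse_end + geom$length / 1000 / spec$true_pwv)
    warning("acquisition window shorter than pulse duration plus distal transit delay; the wave never fully arrives at the far end")

  dims <- c(nx, ny, nz, n_t)
  vx <- array(0, dims); vy <- array(0, dims); vz <- array(0, dims)
  n_vox <- nx * ny * nz
  for (k in seq_len(n_t)) {
    mag <- pulse_waveform(t_k[k] - delay, spec$onset_s, spec$upstroke_s,
                          spec$downstroke_s, spec$peak_velocity) * prof
    idx <- (k - 1) * n_vox
    vx[idx + seq_len(n_vox)] <- mag * cl$tangent[, 1]
    vy[idx + seq_len(n_vox)] <- mag * cl$tangent[, 2]
    vz[idx + seq_len(n_vox)] <- mag * cl$tangent[, 3]
  }

  if (!is.null(spec$eddy)) {
    stopifnot(length(spec$eddy) == 3)
    comps <- list(vx, vy, vz)
    for (c_i in 1:3) {
      b <- spec$eddy[[c_i]]
      off <- b[1] + b[2] * pts[, 1] + b[3] * pts[, 2] + b[4] * pts[, 3]
      comps[[c_i]] <- comps[[c_i]] + array(off, dims)  # static in time
    }
    vx <- comps[[1]]; vy <- comps[[2]]; vz <- comps[[3]]
  }

  if (spec$noise_sd > 0 || spec$wrap_enabled) {
    res <- with_seed(spec$seed, {
      if (spec$noise_sd > 0) {
        vx <- vx + array(stats::rnorm(length(vx), 0, spec$noise_sd), dims)
        vy <- vy + array(stats::rnorm(length(vy), 0, spec$noise_sd), dims)
        vz <- vz + array(stats::rnorm(length(vz), 0, spec$noise_sd), dims)
      }
      list(vx, vy, vz)
    })
    vx <- res[[1]]; vy <- res[[2]]; vz <- res[[3]]
    if (spec$wrap_enabled) {
      wrap <- function(v) ((v + spec$venc) %% (2 * spec$venc)) - spec$venc
      vx <- wrap(vx); vy <- wrap(vy); vz <- wrap(vz)
    }
  }

  s_grid <- seq(0, geom$length, by = 1)
  cp <- candy_cane_point(geom, s_grid)
  truth_cl <- centerline(cp$point, tangents = cp$tangent)

  list(field = velocity_field(vx, vy, vz, sp, spec$dt_ms, spec$venc),
       centerline = truth_cl,
       lumen = lumen_mask(array(inside, c(nx, ny, nz)), sp),
       geometry = geom,
       spec = spec)
}
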