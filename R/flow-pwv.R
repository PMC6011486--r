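#' Flow waveform on an analysis plane
#'
#' Integrates the through-plane velocity over the lumen cross-section at
#' every cardiac phase: `Q_k = sum(v . n) * cell_area`, reported in mL/s.
#' Velocities are sampled trilinearly on the plane grid.
#'
#' @param field A [velocity_field()].
#' @param plane An analysis plane from [place_planes()].
#' @param guard_cells cells of dilation applied to the lumen cross-section
#'   before integrating (default 1). Interpolation spreads the flux of
#'   wall-adjacent voxels across the lumen contour; without a guard band
#'   that partial-volume flux is clipped and plug flow under-reads by a few
#'   percent.
#' @return An object of class `flow_waveform`: `plane_id`, `s_mm`, `t_s`
#'   (uniform grid), `q_ml_s`.
#' @export
extract_flow_waveform <- function(field, plane, guard_cells = 1L) {
  stopifnot(inherits(field, "velocity_field"), inherits(plane, "analysis_plane"))
  if (!any(plane$lumen_grid)) stop("plane has an empty lumen cross-section")
  d <- dim(field$vx)
  offs <- seq(-plane$half_width_mm, plane$half_width_mm, by = plane$grid_mm)
  uv <- as.matrix(expand.grid(u = offs, v = offs))
  lum <- plane$lumen_grid
  for (i in seq_len(guard_cells)) lum <- dilate2_box(lum)
  sel <- as.vector(lum)
  pts <- matrix(plane$center, sum(sel), 3, byrow = TRUE) +
    uv[sel, 1, drop = FALSE] %*% t(plane$e1) +
    uv[sel, 2, drop = FALSE] %*% t(plane$e2)
  if (any(pts < -1e-6) ||
      any(sweep(pts, 2, (d[1:3] - 1) * field$spacing, `-`) > 1e-6)) {
    # tolerate grid corners poking out; require the plane centre inside
    ctr_vox <- plane$center / field$spacing
    if (any(ctr_vox < 0) || any(ctr_vox > d[1:3] - 1))
      stop("analysis plane lies outside the velocity field extent")
  }
  vox <- sweep(pts, 2, field$spacing, `/`)
  n_t <- d[4]
  n_vox3 <- prod(d[1:3])
  q <- numeric(n_t)
  cell <- plane$grid_mm^2                     # mm^2
  for (k in seq_len(n_t)) {
    # velocity in m/s = 1000 mm/s; Q [mL/s] = sum(v_mm_s * area_mm2) / 1000
    vk <- interp3(array(field$vx[(k - 1) * n_vox3 + seq_len(n_vox3)], d[1:3]), vox) * plane$normal[1] +
          interp3(array(field$vy[(k - 1) * n_vox3 + seq_len(n_vox3)], d[1:3]), vox) * plane$normal[2] +
          interp3(array(field$vz[(k - 1) * n_vox3 + seq_len(n_vox3)], d[1:3]), vox) * plane$normal[3]
    q[k] <- sum(vk) * cell                    # (m/s * mm^2) = mL/s exactly
  }
  structure(list(plane_id = plane$id, s_mm = plane$s_mm,
                 t_s = phase_times(field), q_ml_s = q),
            class = "flow_waveform")
}

#' Flow waveforms for a set of planes
#'
#' Batched equivalent of [extract_flow_waveform()]: each cardiac phase is
#' sliced from the 4D arrays once and sampled for every plane, which is much
#' faster than per-plane extraction when there are tens of planes.
#'
#' @inheritParams extract_flow_waveform
#' @param planes list of analysis planes from [place_planes()].
#' @return List of `flow_waveform` objects, one per plane.
#' @export
extract_flow_waveforms <- function(field, planes, guard_cells = 1L) {
  stopifnot(inherits(field, "velocity_field"))
  d <- dim(field$vx)
  n3 <- prod(d[1:3])
  pt_list <- lapply(planes, function(plane) {
    if (!any(plane$lumen_grid)) stop("plane has an empty lumen cross-section")
    offs <- seq(-plane$half_width_mm, plane$half_width_mm, by = plane$grid_mm)
    uv <- as.matrix(expand.grid(u = offs, v = offs))
    lum <- plane$lumen_grid
    for (i in seq_len(guard_cells)) lum <- dilate2_box(lum)
    sel <- as.vector(lum)
    pts <- matrix(plane$center, sum(sel), 3, byrow = TRUE) +
      uv[sel, 1, drop = FALSE] %*% t(plane$e1) +
      uv[sel, 2, drop = FALSE] %*% t(plane$e2)
    sweep(pts, 2, field$spacing, `/`)
  })
  n_pts <- vapply(pt_list, nrow, integer(1))
  vox <- do.call(rbind, pt_list)
  grp <- rep(seq_along(planes), n_pts)
  nrm <- do.call(rbind, lapply(planes, `[[`, "normal"))
  q <- matrix(0, d[4], length(planes))
  for (k in seq_len(d[4])) {
    idx <- (k - 1) * n3 + seq_len(n3)
    vk <- interp3(array(field$vx[idx], d[1:3]), vox) * nrm[grp, 1] +
          interp3(array(field$vy[idx], d[1:3]), vox) * nrm[grp, 2] +
          interp3(array(field$vz[idx], d[1:3]), vox) * nrm[grp, 3]
    q[k, ] <- rowsum(vk, grp)[, 1]
  }
  t_s <- phase_times(field)
  lapply(seq_along(planes), function(i)
    structure(list(plane_id = planes[[i]]$id, s_mm = planes[[i]]$s_mm,
                   t_s = t_s, q_ml_s = q[, i] * planes[[i]]$grid_mm^2),
              class = "flow_waveform"))
}

#' @export
print.flow_waveform <- function(x, ...) {
  cat(sprintf("<flow_waveform> plane %d at s = %.1f mm, peak %.1f mL/s\n",
              x$plane_id, x$s_mm, max(x$q_ml_s)))
  invisible(x)
}

# Locate the systolic upstroke of a single-pulse waveform. Returns the peak
# index, baseline level (median of pre-upstroke samples) and the index of
# the upstroke start (last pre-peak sample at or below the low threshold).
upstroke_window <- function(q) {
  if (max(q) <= min(q)) stop("flat waveform: wave arrival is undefined")
  kp <- which.max(q)
  pre <- q[seq_len(kp)]
  low <- min(pre) + 0.1 * (q[kp] - min(pre))
  below <- which(pre <= low)
  k0 <- if (length(below)) max(below) else 1L
  baseline <- stats::median(q[seq_len(max(k0, 1L))])
  list(peak = kp, start = k0, baseline = baseline)
}

#' Wave arrival by time-to-foot
#'
#' The foot of the systolic upstroke: the intersection of the diastolic
#' baseline (median of pre-upstroke samples) with a straight line fitted to
#' the 20--80% portion of the upstroke. Continuous in the data through
#' linear interpolation of the crossing levels.
#'
#' @param w A [extract_flow_waveform()] result (or any list with `t_s`,
#'   `q_ml_s`).
#' @return Arrival time in seconds.
#' @export
arrival_time_ttf <- function(w) {
  q <- w$q_ml_s; t <- w$t_s
  win <- upstroke_window(q)
  b <- win$baseline; kp <- win$peak
  l20 <- b + 0.2 * (q[kp] - b)
  l80 <- b + 0.8 * (q[kp] - b)
  # continuous crossing times of the two levels on the upstroke
  t_cross <- function(level) {
    ks <- win$start:kp
    above <- which(q[ks] >= level)
    if (!length(above)) return(t[kp])
    k2 <- ks[min(above)]
    if (k2 == ks[1]) return(t[k2])
    k1 <- k2 - 1L
    t[k1] + (level - q[k1]) / (q[k2] - q[k1]) * (t[k2] - t[k1])
  }
  t20 <- t_cross(l20); t80 <- t_cross(l80)
  ks <- win$start:kp
  in_band <- ks[q[ks] >= l20 & q[ks] <= l80]
  # fit to the sampled 20-80% points; fall back to the two crossing times
  # when the upstroke is so steep that no sample falls in the band
  if (length(in_band) >= 2) {
    fit <- stats::lm.fit(cbind(1, t[in_band]), q[in_band])$coefficients
    slope <- fit[2]; icpt <- fit[1]
  } else {
    slope <- (l80 - l20) / (t80 - t20)
    icpt <- l20 - slope * t20
  }
  if (!is.finite(slope) || slope <= 0) stop("no rising upstroke found")
  unname((b - icpt) / slope)
}

#' Wave arrival by the half-peak (50%) rule
#'
#' First upstroke crossing of `baseline + 0.5 * (peak - baseline)`, located
#' by linear interpolation between the bracketing samples.
#'
#' @inheritParams arrival_time_ttf
#' @return Arrival time in seconds.
#' @export
arrival_time_half_peak <- function(w) {
  q <- w$q_ml_s; t <- w$t_s
  win <- upstroke_window(q)
  level <- win$baseline + 0.5 * (q[win$peak] - win$baseline)
  ks <- win$start:win$peak
  above <- which(q[ks] >= level)
  k2 <- ks[min(above)]
  if (k2 == ks[1]) return(t[k2])
  k1 <- k2 - 1L
  unname(t[k1] + (level - q[k1]) / (q[k2] - q[k1]) * (t[k2] - t[k1]))
}

#' Inter-plane wave delay by cross-correlation
#'
#' Lag maximising the normalised cross-correlation between a waveform and
#' the reference waveform, refined to sub-sample precision by a parabola
#' through the correlation peak and its two neighbours.
#'
#' @param w,ref Flow waveforms on the same uniform time grid.
#' @param max_lag maximum integer lag searched (samples); default half the
#'   series length.
#' @return Lag of `w` behind `ref`, in seconds (positive when `w` is the
#'   more distal, later waveform).
#' @export
arrival_shift_xcor <- function(w, ref, max_lag = NULL) {
  a <- ref$q_ml_s; b <- w$q_ml_s
  if (length(a) != length(b) || max(abs(w$t_s - ref$t_s)) > 1e-9)
    stop("waveforms must share one time grid")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant waveform: cross-correlation undefined")
  n <- length(a)
  dt <- w$t_s[2] - w$t_s[1]
  if (is.null(max_lag)) max_lag <- n %/% 2
  lags <- (-max_lag):max_lag
  ncc <- vapply(lags, function(l) {
    ia <- seq_len(n)
    ib <- ia + l
    ok <- ib >= 1 & ib <= n
    if (sum(ok) < 3) return(-Inf)
    x <- a[ia[ok]]; y <- b[ib[ok]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(-Inf)
    stats::cor(x, y)
  }, numeric(1))
  i <- which.max(ncc)
  lag <- lags[i]
  # parabolic sub-sample refinement through the peak and neighbours
  delta <- 0
  if (i > 1 && i < length(lags) && is.finite(ncc[i - 1]) && is.finite(ncc[i + 1])) {
    denom <- ncc[i - 1] - 2 * ncc[i] + ncc[i + 1]
    if (denom < 0) delta <- 0.5 * (ncc[i - 1] - ncc[i + 1]) / denom
  }
  (lag + delta) * dt
}

#' Arrival-time table for a set of planes
#'
#' Applies one wave-arrival detector to every plane waveform. For
#' `"xcor"` the lag is measured against the most proximal plane (the first
#' waveform), matching a transit-time fit through lags rather than absolute
#' arrival times.
#'
#' @param waveforms list of flow waveforms ordered along the vessel.
#' @param method one of `"ttf"`, `"half_peak"`, `"xcor"`.
#' @return An object of class `arrival_times`: data.frame with `s_mm`,
#'   `tau_s`, plus a `method` attribute.
#' @export
arrival_times <- function(waveforms, method = c("ttf", "half_peak", "xcor")) {
  method <- match.arg(method)
  tau <- switch(method,
    ttf = vapply(waveforms, arrival_time_ttf, numeric(1)),
    half_peak = vapply(waveforms, arrival_time_half_peak, numeric(1)),
    xcor = vapply(waveforms, arrival_shift_xcor, numeric(1), ref = waveforms[[1]])
  )
  out <- data.frame(s_mm = vapply(waveforms, `[[`, numeric(1), "s_mm"),
                    tau_s = tau)
  structure(out, method = method, class = c("arrival_times", "data.frame"))
}

#' Fit pulse wave velocity from arrival times
#'
#' Ordinary least squares of arrival time (s) on centerline arc length
#' (mm); PWV is the inverse slope, `1 / (slope * 1000)` m/s. An optional
#' robust mode drops planes whose residual exceeds 3 median absolute
#' deviations and refits once.
#'
#' @param arrivals An [arrival_times()] table (columns `s_mm`, `tau_s`).
#' @param robust drop >3-MAD residual outliers and refit once.
#' @return An object of class `pwv_estimate`: `pwv` (m/s), `slope_s_per_mm`,
#'   `intercept_s`, `r_squared`, `n_planes`, `method`, `valid` (FALSE when
#'   the fitted slope is non-positive, i.e. a non-physical wave direction).
#' @export
fit_pwv <- function(arrivals, robust = FALSE) {
  df <- as.data.frame(arrivals)
  df <- df[is.finite(df$tau_s) & is.finite(df$s_mm), ]
  if (nrow(df) < 2) stop("PWV fit needs at least 2 planes with finite arrival times")
  fit <- stats::lm(tau_s ~ s_mm, data = df)
  if (robust) {
    res <- stats::residuals(fit)
    md <- stats::mad(res)
    keep <- if (md > 0) abs(res) <= 3 * md else rep(TRUE, nrow(df))
    if (sum(keep) >= 2 && any(!keep)) fit <- stats::lm(tau_s ~ s_mm, data = df[keep, ])
    df <- df[keep, , drop = FALSE]
  }
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  # a slope at numerical zero (or negative) means no physical forward wave
  valid <- is.finite(slope) && slope > 1e-10
  structure(list(
    pwv = if (valid) 1 / (slope * 1000) else NA_real_,
    slope_s_per_mm = slope,
    intercept_s = unname(stats::coef(fit)[1]),
    r_squared = r2,
    n_planes = nrow(df),
    method = attr(arrivals, "method") %||% "unknown",
    valid = valid
  ), class = "pwv_estimate")
}

#' @export
print.pwv_estimate <- function(x, ...) {
  cat(sprintf("<pwv_estimate> %s: %s m/s (R^2 = %.3f, %d planes)%s\n",
              x$method,
              if (is.na(x$pwv)) "NA" else sprintf("%.2f", x$pwv),
              x$r_squared, x$n_planes,
              if (!x$valid) " [invalid: non-positive slope]" else ""))
  invisible(x)
}

#' End-to-end PWV estimation from a velocity field
#'
#' Convenience pipeline: segment the lumen (unless a mask is supplied),
#' extract the centerline between the two seed points, distribute analysis
#' planes at the requested spacing, integrate flow waveforms, and fit PWV
#' with each requested wave-arrival method.
#'
#' @param field A preprocessed [velocity_field()].
#' @param start_mm,end_mm centerline seed points (world mm).
#' @param lumen optional precomputed [lumen_mask()].
#' @param spacing_mm inter-plane distance (default 5 mm).
#' @param methods wave-arrival detectors to run.
#' @param s_trim_mm arc length trimmed off both centerline ends before
#'   placing planes (planes too close to the seeds sit in partly
#'   interpolated flow); default 10 mm.
#' @param threshold_fraction passed to [segment_lumen()].
#' @return Named list of [fit_pwv()] estimates, plus attributes
#'   `"waveforms"`, `"planes"`, and `"centerline"`.
#' @export
estimate_pwv <- function(field, start_mm, end_mm, lumen = NULL,
                         spacing_mm = 5, methods = c("ttf", "half_peak", "xcor"),
                         s_trim_mm = 10, threshold_fraction = 0.2) {
  if (is.null(lumen)) lumen <- segment_lumen(field, threshold_fraction)
  cl <- extract_centerline(lumen, start_mm, end_mm)
  planes <- place_planes(cl, lumen, spacing_mm = spacing_mm,
                         s_start = s_trim_mm, s_end = cl$length - s_trim_mm)
  waveforms <- extract_flow_waveforms(field, planes)
  out <- lapply(methods, function(m) fit_pwv(arrival_times(waveforms, m)))
  names(out) <- methods
  attr(out, "waveforms") <- waveforms
  attr(out, "planes") <- planes
  attr(out, "centerline") <- cl
  out
}
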