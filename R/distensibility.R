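#' Vessel contour on a CINE frame
#'
#' A closed region of interest, stored either as a polygon (n x 2 matrix of
#' 0-based pixel coordinates, implicitly closed) or as a logical pixel
#' mask. Propagated contours are polygons, whose vertices move with the
#' estimated displacement field at sub-pixel precision.
#'
#' @param frame 1-based frame index the contour belongs to.
#' @param polygon n x 2 matrix of vertices (0-based pixel coords), or `NULL`.
#' @param mask logical matrix, or `NULL`. Exactly one of `polygon`/`mask`.
#' @return An object of class `roi_contour`.
#' @export
roi_contour <- function(frame, polygon = NULL, mask = NULL) {
  if (is.null(polygon) == is.null(mask))
    stop("provide exactly one of polygon or mask")
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    stopifnot(ncol(polygon) == 2, nrow(polygon) >= 3)
  }
  structure(list(frame = frame, polygon = polygon, mask = mask),
            class = "roi_contour")
}

#' Circular contour helper
#'
#' @param frame frame index.
#' @param center_px disk centre (0-based pixel coords).
#' @param radius_px radius in pixels.
#' @param n_vertices polygon resolution.
#' @return A polygon [roi_contour()].
#' @export
circle_contour <- function(frame, center_px, radius_px, n_vertices = 180) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  roi_contour(frame, polygon = cbind(center_px[1] + radius_px * cos(th),
                                     center_px[2] + radius_px * sin(th)))
}

# Shoelace area of a polygon (pixel^2, sign-free).
polygon_area_px2 <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Contour area
#'
#' Polygon contours use the exact shoelace area of the vertex chain; mask
#' contours use pixel summation. Both are converted with the pixel spacing.
#'
#' @param contour A [roi_contour()].
#' @param spacing_mm pixel spacing (mm).
#' @return Area in mm^2.
#' @export
contour_area <- function(contour, spacing_mm) {
  if (!is.null(contour$polygon))
    polygon_area_px2(contour$polygon) * spacing_mm^2
  else sum(contour$mask) * spacing_mm^2
}

#' Propagate a reference contour through a CINE series
#'
#' Frame-to-frame displacement fields are estimated with the phase-based
#' registration ([register_phase()]) and applied serially, carrying the
#' reference-frame contour through the whole cardiac cycle (wrapping from
#' the last frame back to frame 1 when the reference is not the first
#' frame). Deterministic.
#'
#' @param cine A [cine_series()].
#' @param c0 reference [roi_contour()] (polygon form) on frame `c0$frame`.
#' @param ... passed to [register_phase()].
#' @return List of [roi_contour()]s, one per frame, in frame order; the
#'   entry at the reference frame is `c0` itself.
#' @export
propagate_contour <- function(cine, c0, ...) {
  stopifnot(inherits(cine, "cine_series"), inherits(c0, "roi_contour"))
  if (is.null(c0$polygon)) stop("propagation needs a polygon contour")
  n_t <- dim(cine$frames)[3]
  if (c0$frame < 1 || c0$frame > n_t) stop("reference frame outside the series")
  d <- dim(cine$frames)[1:2]
  if (any(c0$polygon < 0) || any(c0$polygon[, 1] > d[1] - 1) ||
      any(c0$polygon[, 2] > d[2] - 1))
    stop("reference contour outside the image bounds")
  out <- vector("list", n_t)
  out[[c0$frame]] <- c0
  order_k <- ((c0$frame - 1 + seq_len(n_t - 1)) %% n_t) + 1  # serial, wrapping
  prev <- c0$frame
  poly <- c0$polygon
  for (k in order_k) {
    u <- register_phase(cine$frames[, , prev], cine$frames[, , k], ...)
    disp <- cbind(interp2(u$ux, poly), interp2(u$uy, poly))
    poly <- poly + disp
    if (any(poly < 0) || any(poly[, 1] > d[1] - 1) || any(poly[, 2] > d[2] - 1))
      stop(sprintf("contour driven outside the image bounds at frame %d", k))
    out[[k]] <- roi_contour(k, polygon = poly)
    prev <- k
  }
  out
}

#' Per-phase equivalent diameter curve
#'
#' @param d_mm per-phase equivalent diameters (mm).
#' @param end_diastolic_frame frame whose diameter defines `Dd`; default the
#'   frame of minimum diameter.
#' @return An object of class `diameter_curve`: `d_mm`, `dd_mm` (end-
#'   diastolic diameter), `delta_d_mm` (systolic max minus `Dd`),
#'   `end_diastolic_frame`.
#' @export
diameter_curve <- function(d_mm, end_diastolic_frame = NULL) {
  if (length(d_mm) < 2) stop("a diameter curve needs at least 2 phases")
  if (any(d_mm <= 0)) stop("diameters must be positive")
  if (is.null(end_diastolic_frame)) end_diastolic_frame <- which.min(d_mm)
  dd <- d_mm[end_diastolic_frame]
  structure(list(d_mm = d_mm, dd_mm = dd, delta_d_mm = max(d_mm) - dd,
                 end_diastolic_frame = end_diastolic_frame),
            class = "diameter_curve")
}

#' @export
print.diameter_curve <- function(x, ...) {
  cat(sprintf("<diameter_curve> %d phases, Dd = %.2f mm, delta d = %.2f mm\n",
              length(x$d_mm), x$dd_mm, x$delta_d_mm))
  invisible(x)
}

#' Equivalent diameters from tracked contours
#'
#' Areas are measured per contour ([contour_area()]) and converted to the
#' diameter of the circle of equal area, `d = 2 * sqrt(A / pi)`.
#'
#' @param contours list of [roi_contour()]s (one per phase).
#' @param spacing_mm pixel spacing.
#' @param end_diastolic_frame passed to [diameter_curve()]; default the
#'   minimum-diameter frame.
#' @return A [diameter_curve()].
#' @export
diameter_from_area <- function(contours, spacing_mm, end_diastolic_frame = NULL) {
  if (length(contours) < 2) stop("need at least 2 contours")
  a <- vapply(contours, contour_area, numeric(1), spacing_mm = spacing_mm)
  if (any(a <= 0)) stop("empty contour encountered")
  diameter_curve(2 * sqrt(a / pi), end_diastolic_frame)
}

MMHG_TO_KPA <- 0.133322

#' Brachial blood pressure record
#'
#' @param systolic_mmhg,diastolic_mmhg pressures in mmHg; when two readings
#'   (before and after the scan) are supplied their average is used.
#' @return An object of class `blood_pressure` with `systolic`, `diastolic`
#'   and `pulse_pressure` (all mmHg).
#' @export
blood_pressure <- function(systolic_mmhg, diastolic_mmhg) {
  s <- mean(systolic_mmhg); d <- mean(diastolic_mmhg)
  if (!(s > d && d > 0)) stop("need systolic > diastolic > 0")
  structure(list(systolic = s, diastolic = d, pulse_pressure = s - d),
            class = "blood_pressure")
}

#' Aortic distensibility coefficient
#'
#' `DC = (2 * delta_d / Dd) / delta_P`, with the pulse pressure converted
#' from mmHg to kPa (1 mmHg = 0.133322 kPa), reported in units of
#' `10^-3 / kPa`.
#'
#' @param curve A [diameter_curve()].
#' @param bp A [blood_pressure()].
#' @param site `"ascending"` or `"descending"` aorta tag.
#' @return An object of class `dc_result`: `dc` (10^-3 / kPa), `site`, and
#'   the inputs `delta_d_mm`, `dd_mm`, `pulse_pressure_mmhg`,
#'   `pulse_pressure_kpa`.
#' @export
distensibility_coefficient <- function(curve, bp, site = c("ascending", "descending")) {
  site <- match.arg(site)
  stopifnot(inherits(curve, "diameter_curve"), inherits(bp, "blood_pressure"))
  dp_kpa <- bp$pulse_pressure * MMHG_TO_KPA
  if (dp_kpa <= 0) stop("pulse pressure must be positive")
  dc <- (2 * curve$delta_d_mm / curve$dd_mm) / dp_kpa * 1000
  structure(list(dc = dc, site = site,
                 delta_d_mm = curve$delta_d_mm, dd_mm = curve$dd_mm,
                 pulse_pressure_mmhg = bp$pulse_pressure,
                 pulse_pressure_kpa = dp_kpa,
                 mmhg_to_kpa = MMHG_TO_KPA),
            class = "dc_result")
}

#' @export
print.dc_result <- function(x, ...) {
  cat(sprintf("<dc_result> %s aorta: DC = %.1f x 10^-3/kPa (delta d %.2f mm, Dd %.2f mm, dP %.1f mmHg)\n",
              x$site, x$dc, x$delta_d_mm, x$dd_mm, x$pulse_pressure_mmhg))
  invisible(x)
}

#' End-to-end distensibility from a CINE series
#'
#' Propagates the reference contour, converts areas to equivalent
#' diameters, and computes the distensibility coefficient.
#'
#' @param cine A [cine_series()].
#' @param c0 reference contour at a diastolic frame.
#' @param bp A [blood_pressure()].
#' @param site vessel site tag.
#' @param end_diastolic_frame passed to [diameter_from_area()].
#' @param ... passed to [register_phase()].
#' @return A `dc_result` with the measured [diameter_curve()] attached as
#'   attribute `"curve"`.
#' @export
estimate_dc <- function(cine, c0, bp, site = "ascending",
                        end_diastolic_frame = NULL, ...) {
  contours <- propagate_contour(cine, c0, ...)
  curve <- diameter_from_area(contours, cine$spacing_mm, end_diastolic_frame)
  out <- distensibility_coefficient(curve, bp, site)
  attr(out, "curve") <- curve
  out
}
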