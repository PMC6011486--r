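#' Analysis plane normal to the centerline
#'
#' A plane is defined by its centre (on the centerline), unit normal (the
#' local tangent), two in-plane orthonormal basis vectors, and a square
#' sampling grid carrying the lumen cross-section.
#'
#' @name analysis_plane
#' @keywords internal
NULL

new_analysis_plane <- function(id, center, normal, e1, e2, s_mm,
                               grid_mm, half_width_mm, lumen_grid) {
  structure(list(id = id, center = center, normal = normal, e1 = e1, e2 = e2,
                 s_mm = s_mm, grid_mm = grid_mm, half_width_mm = half_width_mm,
                 lumen_grid = lumen_grid),
            class = "analysis_plane")
}

#' @export
print.analysis_plane <- function(x, ...) {
  cat(sprintf("<analysis_plane> #%d at s = %.1f mm, lumen area %.0f mm^2\n",
              x$id, x$s_mm, sum(x$lumen_grid) * x$grid_mm^2))
  invisible(x)
}

#' Lumen cross-sectional area of a plane
#' @param plane An `analysis_plane`.
#' @return Area in mm^2.
#' @export
plane_area <- function(plane) sum(plane$lumen_grid) * plane$grid_mm^2

# orthonormal in-plane basis for a unit normal
plane_basis <- function(normal) {
  a <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- pracma_cross(normal, a)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- pracma_cross(normal, e1)
  list(e1 = e1, e2 = e2 / sqrt(sum(e2^2)))
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

#' Distribute analysis planes along a centerline
#'
#' Planes are placed at arc lengths `s_start, s_start + spacing, ...` up to
#' `s_end` (count = `floor((s_end - s_start) / spacing) + 1`), each oriented
#' normal to the local centerline tangent. The lumen cross-section is
#' obtained by sampling the mask onto the in-plane grid and keeping the
#' connected component containing the centerline point.
#'
#' @param cl A [centerline()].
#' @param lumen A [lumen_mask()] (same world frame as the centerline).
#' @param spacing_mm inter-plane distance along the centerline (default 5 mm).
#' @param s_start,s_end arc-length range (mm); defaults to the whole
#'   centerline.
#' @param half_width_mm half the side of the square in-plane sampling grid;
#'   default twice the estimated lumen radius (`sqrt(V / (pi * L))`).
#' @param grid_mm in-plane sample spacing; default the smallest voxel size.
#' @return List of `analysis_plane` objects.
#' @export
place_planes <- function(cl, lumen, spacing_mm = 5, s_start = 0,
                         s_end = NULL, half_width_mm = NULL, grid_mm = NULL) {
  stopifnot(inherits(cl, "centerline"), inherits(lumen, "lumen_mask"))
  if (is.null(s_end)) s_end <- cl$length
  if (spacing_mm <= 0) stop("plane spacing must be positive")
  if (s_start < 0 || s_end > cl$length + 1e-6 || s_start >= s_end)
    stop("need 0 <= s_start < s_end <= centerline length")
  if (spacing_mm > s_end - s_start) {
    warning("plane spacing exceeds the requested segment; returning a single plane (PWV fitting requires at least 2)")
    n <- 1L
  } else {
    n <- as.integer(floor((s_end - s_start) / spacing_mm + 1e-9)) + 1L
  }
  s_vals <- s_start + (seq_len(n) - 1) * spacing_mm

  if (is.null(grid_mm)) grid_mm <- min(lumen$spacing)
  if (is.null(half_width_mm)) {
    vol <- sum(lumen$mask) * prod(lumen$spacing)
    r_est <- sqrt(vol / (pi * cl$length))
    half_width_mm <- 2 * r_est
  }
  at <- centerline_at(cl, s_vals)
  offs <- seq(-half_width_mm, half_width_mm, by = grid_mm)
  uv <- as.matrix(expand.grid(u = offs, v = offs))
  n_grid <- length(offs)
  mask_num <- array(as.numeric(lumen$mask), dim(lumen$mask))

  lapply(seq_len(n), function(i) {
    nrm <- at$tangent[i, ]
    b <- plane_basis(nrm)
    pts <- matrix(at$point[i, ], nrow(uv), 3, byrow = TRUE) +
      uv[, 1] %*% t(b$e1) + uv[, 2] %*% t(b$e2)
    vox <- sweep(pts, 2, lumen$spacing, `/`)
    samp <- interp3(mask_num, vox) >= 0.5
    grid <- matrix(samp, n_grid, n_grid)
    ctr <- c(which.min(abs(offs)), which.min(abs(offs)))
    if (!grid[ctr[1], ctr[2]] && any(grid)) {
      # centerline point fell on a sub-voxel gap; seed from the nearest
      # in-lumen grid sample instead
      w <- which(grid, arr.ind = TRUE)
      dd <- (w[, 1] - ctr[1])^2 + (w[, 2] - ctr[2])^2
      ctr <- as.integer(w[which.min(dd), ])
    }
    lum <- if (any(grid) && grid[ctr[1], ctr[2]])
      component_containing2(grid, ctr) else matrix(FALSE, n_grid, n_grid)
    new_analysis_plane(i, at$point[i, ], nrm, b$e1, b$e2, s_vals[i],
                       grid_mm, half_width_mm, lum)
  })
}
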