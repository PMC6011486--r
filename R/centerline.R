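#' Vessel centerline
#'
#' An ordered polyline in world coordinates (mm) with cumulative arc length
#' and unit tangents.
#'
#' @param points n x 3 matrix of world coordinates (mm).
#' @param tangents optional n x 3 matrix of tangents; computed by central
#'   differences when missing. Tangents are normalised to unit length.
#' @return An object of class `centerline` with elements `points`, `s`
#'   (cumulative arc length, mm, `s[1] = 0`), `tangents`, and `length` (mm).
#' @export
centerline <- function(points, tangents = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 2)
  seg <- sqrt(rowSums(diff(points)^2))
  if (any(seg == 0)) stop("centerline points must be distinct consecutive positions")
  s <- c(0, cumsum(seg))
  if (is.null(tangents)) tangents <- central_diff_tangents(points)
  tangents <- normalize_rows(as.matrix(tangents))
  structure(list(points = points, s = s, tangents = tangents,
                 length = s[length(s)]), class = "centerline")
}

central_diff_tangents <- function(points) {
  n <- nrow(points)
  tg <- matrix(0, n, 3)
  tg[2:(n - 1), ] <- points[3:n, ] - points[1:(n - 2), ]
  tg[1, ] <- points[2, ] - points[1, ]
  tg[n, ] <- points[n, ] - points[n - 1, ]
  tg
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, arc length %.1f mm\n",
              nrow(x$points), x$length))
  invisible(x)
}

# Linear interpolation of position and tangent at arc lengths s_query.
centerline_at <- function(cl, s_query) {
  s_query <- pmin(pmax(s_query, 0), cl$length)
  p <- sapply(1:3, function(j) stats::approx(cl$s, cl$points[, j], s_query)$y)
  tg <- sapply(1:3, function(j) stats::approx(cl$s, cl$tangents[, j], s_query)$y)
  p <- matrix(p, ncol = 3); tg <- matrix(tg, ncol = 3)
  list(point = p, tangent = normalize_rows(tg))
}

#' Extract the aortic centerline from a lumen mask
#'
#' Builds a voxel graph over the lumen in which steps are weighted by the
#' inverse squared distance to the vessel boundary, finds the shortest path
#' between the two seed points (so the path hugs the medial axis), smooths
#' each coordinate with a spline against arc length, and resamples to a
#' uniform step. This is a reproducible stand-in for the interactive
#' centerline tool of clinical software: the user contributes only a start
#' and an end point inside the lumen.
#'
#' @param lumen A [lumen_mask()].
#' @param start_mm,end_mm world coordinates (mm) of seed points inside the
#'   lumen (aortic root and diaphragm level, conventionally).
#' @param step_mm resampling step of the returned polyline (mm).
#' @param smooth_df degrees of freedom of the smoothing spline; default
#'   scales with path length (one df per ~5 mm), enough to follow the arch
#'   curvature while ironing out voxel zigzag.
#' @return A [centerline()].
#' @export
extract_centerline <- function(lumen, start_mm, end_mm, step_mm = 1,
                               smooth_df = NULL) {
  stopifnot(inherits(lumen, "lumen_mask"))
  mask <- lumen$mask
  sp <- lumen$spacing
  d <- dim(mask)
  to_idx <- function(w) {
    i <- round(w / sp)
    if (any(i < 0) || any(i >= d)) stop("seed point outside the image volume")
    as.integer(i)
  }
  i_start <- to_idx(start_mm); i_end <- to_idx(end_mm)
  lin <- function(i) 1L + i[1] + d[1] * (i[2] + d[2] * i[3])
  if (!mask[lin(i_start)] || !mask[lin(i_end)])
    stop("seed points must lie inside the lumen mask")
  comp <- flood_fill6(mask, lin(i_start))
  if (!comp[lin(i_end)])
    stop("start and end seeds are not connected within the lumen mask")
  mask <- comp

  depth <- erosion_depth(mask)              # city-block voxel distance to wall
  vox <- which(mask)
  node_id <- array(NA_integer_, d)
  node_id[vox] <- seq_along(vox)
  i0 <- vox - 1L
  coord <- cbind(i0 %% d[1], (i0 %/% d[1]) %% d[2], i0 %/% (d[1] * d[2]))

  edges <- NULL; weights <- NULL
  step_lin <- c(1L, d[1], d[1] * d[2])
  for (dmi in 1:3) {
    ok <- coord[, dmi] < d[dmi] - 1L
    nb <- vox[ok] + step_lin[dmi]
    ok2 <- mask[nb]
    a <- node_id[vox[ok][ok2]]; b <- node_id[nb[ok2]]
    # favour deep (medial) voxels: weight = step length / mean depth^2
    w <- sp[dmi] / ((depth[vox[ok][ok2]] + depth[nb[ok2]]) / 2)^2
    edges <- c(edges, rbind(a, b))
    weights <- c(weights, w)
  }
  g <- igraph::make_graph(edges, n = length(vox), directed = FALSE)
  path <- igraph::shortest_paths(g, from = node_id[lin(i_start)],
                                 to = node_id[lin(i_end)],
                                 weights = weights, output = "vpath")$vpath[[1]]
  path <- as.integer(path)
  if (length(path) < 2) stop("no centerline path found between the seeds")
  pw <- sweep(coord[path, , drop = FALSE], 2, sp, `*`)   # world mm

  # spline-smooth each coordinate against cumulative chord length
  cs <- c(0, cumsum(sqrt(rowSums(diff(pw)^2))))
  if (is.null(smooth_df))
    smooth_df <- max(8, min(round(cs[length(cs)] / 5), length(path) - 4))
  sm <- sapply(1:3, function(j) {
    if (length(path) <= smooth_df + 2) return(pw[, j])
    stats::predict(stats::smooth.spline(cs, pw[, j], df = smooth_df), cs)$y
  })
  # resample to uniform arc-length step on the smoothed curve
  cs2 <- c(0, cumsum(sqrt(rowSums(diff(sm)^2))))
  s_out <- seq(0, cs2[length(cs2)], by = step_mm)
  res <- sapply(1:3, function(j) stats::approx(cs2, sm[, j], s_out)$y)
  centerline(matrix(res, ncol = 3))
}
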