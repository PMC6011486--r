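# Shift a 3D logical/numeric array by one voxel along a dimension, padding
# with `fill`. Used by morphology and connected-component routines.
shift3 <- function(a, dim, by, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  src <- lapply(d, seq_len)
  dst <- src
  if (by > 0) {
    dst[[dim]] <- (1 + by):d[dim]
    src[[dim]] <- 1:(d[dim] - by)
  } else if (by < 0) {
    dst[[dim]] <- 1:(d[dim] + by)
    src[[dim]] <- (1 - by):d[dim]
  } else {
    return(a)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# 6-connected binary dilation / erosion on a 3D logical array.
dilate6 <- function(mask) {
  out <- mask
  for (dm in 1:3) for (by in c(-1L, 1L)) out <- out | shift3(mask, dm, by)
  out
}

erode6 <- function(mask) {
  out <- mask
  for (dm in 1:3) for (by in c(-1L, 1L)) out <- out & shift3(mask, dm, by, fill = FALSE)
  out
}

# Morphological closing (dilate then erode), `iter` rounds of each.
close6 <- function(mask, iter = 1L) {
  for (i in seq_len(iter)) mask <- dilate6(mask)
  for (i in seq_len(iter)) mask <- erode6(mask)
  mask
}

# Distance to background in 6-connected erosion steps (city-block radius,
# voxel units). 0 outside the mask, 1 on the boundary layer, etc.
erosion_depth <- function(mask) {
  depth <- array(0L, dim(mask))
  cur <- mask
  level <- 0L
  while (any(cur)) {
    level <- level + 1L
    nxt <- erode6(cur)
    depth[cur & !nxt] <- level
    cur <- nxt
  }
  depth
}

# Flood fill over the 6-neighbourhood from linear-index seeds; returns a
# logical array marking the connected component(s) containing the seeds.
flood_fill6 <- function(mask, seeds) {
  d <- dim(mask)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  visited <- array(FALSE, d)
  seeds <- seeds[mask[seeds]]
  if (length(seeds) == 0L) return(visited)
  visited[seeds] <- TRUE
  frontier <- seeds
  # precompute index coordinates lazily from linear indices
  while (length(frontier) > 0L) {
    i0 <- (frontier - 1L)
    ix <- i0 %% nx
    iy <- (i0 %/% nx) %% ny
    iz <- i0 %/% (nx * ny)
    cand <- c(
      frontier[ix > 0L] - 1L, frontier[ix < nx - 1L] + 1L,
      frontier[iy > 0L] - nx, frontier[iy < ny - 1L] + nx,
      frontier[iz > 0L] - nx * ny, frontier[iz < nz - 1L] + nx * ny
    )
    cand <- unique(cand)
    cand <- cand[mask[cand] & !visited[cand]]
    visited[cand] <- TRUE
    frontier <- cand
  }
  visited
}

# Largest 6-connected component of a 3D logical array.
largest_component6 <- function(mask) {
  remaining <- mask
  best <- NULL
  best_n <- 0L
  while (any(remaining)) {
    seed <- which(remaining)[1L]
    comp <- flood_fill6(remaining, seed)
    n <- sum(comp)
    if (n > best_n) { best <- comp; best_n <- n }
    remaining <- remaining & !comp
  }
  if (is.null(best)) array(FALSE, dim(mask)) else best
}

# 3x3 box dilation of a 2D logical matrix.
dilate2_box <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  pad <- function(a, dr, dc) {
    b <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    b[rs, cs] <- a[rs - dr, cs - dc]
    b
  }
  for (dr in -1:1) for (dc in -1:1)
    if (dr != 0 || dc != 0) out <- out | pad(m, dr, dc)
  out
}

# 4-connected component of a 2D logical matrix containing (row, col) seed.
component_containing2 <- function(mask, seed_rc) {
  nr <- nrow(mask); nc <- ncol(mask)
  visited <- matrix(FALSE, nr, nc)
  s <- (seed_rc[2] - 1L) * nr + seed_rc[1]
  if (!mask[s]) return(visited)
  visited[s] <- TRUE
  frontier <- s
  while (length(frontier) > 0L) {
    i0 <- frontier - 1L
    r <- i0 %% nr
    cc <- i0 %/% nr
    cand <- c(frontier[r > 0L] - 1L, frontier[r < nr - 1L] + 1L,
              frontier[cc > 0L] - nr, frontier[cc < nc - 1L] + nr)
    cand <- unique(cand)
    cand <- cand[mask[cand] & !visited[cand]]
    visited[cand] <- TRUE
    frontier <- cand
  }
  visited
}

# Trilinear interpolation of a 3D array at continuous 0-based voxel
# coordinates (n x 3 matrix). Points outside the grid return `outside`.
interp3 <- function(arr, pts, outside = 0) {
  d <- dim(arr)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  ok <- x >= 0 & y >= 0 & z >= 0 & x <= d[1] - 1 & y <= d[2] - 1 & z <= d[3] - 1
  out <- rep(outside, nrow(pts))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), d[1] - 2); y0 <- pmin(floor(y), d[2] - 2); z0 <- pmin(floor(z), d[3] - 2)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  # linear index of (x0, y0, z0), 1-based
  base <- 1 + x0 + d[1] * (y0 + d[2] * z0)
  sx <- 1; sy <- d[1]; sz <- d[1] * d[2]
  v000 <- arr[base];           v100 <- arr[base + sx]
  v010 <- arr[base + sy];      v110 <- arr[base + sx + sy]
  v001 <- arr[base + sz];      v101 <- arr[base + sx + sz]
  v011 <- arr[base + sy + sz]; v111 <- arr[base + sx + sy + sz]
  val <- v000 * (1 - fx) * (1 - fy) * (1 - fz) + v100 * fx * (1 - fy) * (1 - fz) +
         v010 * (1 - fx) * fy * (1 - fz)       + v110 * fx * fy * (1 - fz) +
         v001 * (1 - fx) * (1 - fy) * fz       + v101 * fx * (1 - fy) * fz +
         v011 * (1 - fx) * fy * fz             + v111 * fx * fy * fz
  out[ok] <- val
  out
}

# Bilinear interpolation of a matrix at continuous 0-based pixel coordinates.
interp2 <- function(img, pts, outside = 0) {
  d <- dim(img)
  x <- pts[, 1]; y <- pts[, 2]
  ok <- x >= 0 & y >= 0 & x <= d[1] - 1 & y <= d[2] - 1
  out <- rep(outside, nrow(pts))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- pmin(floor(x), d[1] - 2); y0 <- pmin(floor(y), d[2] - 2)
  fx <- x - x0; fy <- y - y0
  base <- 1 + x0 + d[1] * y0
  val <- img[base] * (1 - fx) * (1 - fy) + img[base + 1] * fx * (1 - fy) +
         img[base + d[1]] * (1 - fx) * fy + img[base + 1 + d[1]] * fx * fy
  out[ok] <- val
  out
}

normalize_rows <- function(m) m / sqrt(rowSums(m^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
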