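#' Analytic candy-cane aorta geometry
#'
#' The phantom's thoracic aorta: a straight ascending segment, a
#' semicircular arch (in the x-z plane) and a straight descending segment,
#' parameterised by arc length. Supplies exact arc length, closest point
#' and tangent, so phantom fields and truth records share one source.
#'
#' @param ascending_mm,arch_radius_mm,descending_mm segment dimensions (mm).
#' @param origin world position of the ascending-segment root.
#' @return An object of class `candy_cane` with `length` (total arc length,
#'   mm) among its fields.
#' @export
candy_cane <- function(ascending_mm = 60, arch_radius_mm = 35,
                       descending_mm = 130, origin = c(0, 0, 0)) {
  stopifnot(ascending_mm >= 0, arch_radius_mm > 0, descending_mm >= 0)
  La <- ascending_mm; Ra <- arch_radius_mm; Ld <- descending_mm
  structure(list(
    La = La, Ra = Ra, Ld = Ld, origin = as.numeric(origin),
    length = La + pi * Ra + Ld,
    # arch centre sits at the top of the ascending limb
    centre = as.numeric(origin) + c(Ra, 0, La)
  ), class = "candy_cane")
}

#' Point and tangent of a candy-cane geometry at arc length s
#' @param geom A [candy_cane()]. @param s arc lengths (mm), vectorised.
#' @return List with `point` and `tangent` (n x 3 matrices).
#' @export
candy_cane_point <- function(geom, s) {
  s <- pmin(pmax(s, 0), geom$length)
  La <- geom$La; Ra <- geom$Ra
  o <- geom$origin; C <- geom$centre
  n <- length(s)
  p <- matrix(0, n, 3); tg <- matrix(0, n, 3)
  asc <- s <= La
  arch <- s > La & s <= La + pi * Ra
  desc <- s > La + pi * Ra
  if (any(asc)) {
    p[asc, ] <- cbind(o[1], o[2], o[3] + s[asc])
    tg[asc, ] <- matrix(c(0, 0, 1), sum(asc), 3, byrow = TRUE)
  }
  if (any(arch)) {
    th <- pi - (s[arch] - La) / Ra        # theta from pi (asc) to 0 (desc)
    p[arch, ] <- cbind(C[1] + Ra * cos(th), C[2], C[3] + Ra * sin(th))
    tg[arch, ] <- cbind(sin(th), 0, -cos(th))
  }
  if (any(desc)) {
    sd <- s[desc] - La - pi * Ra
    p[desc, ] <- cbind(o[1] + 2 * Ra, o[2], o[3] + La - sd)
    tg[desc, ] <- matrix(c(0, 0, -1), sum(desc), 3, byrow = TRUE)
  }
  list(point = p, tangent = tg)
}

#' Closest-point query against a candy-cane geometry
#' @param geom A [candy_cane()]. @param pts n x 3 matrix of world points (mm).
#' @return List with `dist` (radial distance to the path, mm), `s` (arc
#'   length of the closest path point) and `tangent` (n x 3).
#' @export
candy_cane_closest <- function(geom, pts) {
  o <- geom$origin; C <- geom$centre
  La <- geom$La; Ra <- geom$Ra; Ld <- geom$Ld
  n <- nrow(pts)

  seg_closest <- function(P0, u, L, s0) {
    t <- (pts[, 1] - P0[1]) * u[1] + (pts[, 2] - P0[2]) * u[2] + (pts[, 3] - P0[3]) * u[3]
    t <- pmin(pmax(t, 0), L)
    dx <- pts[, 1] - (P0[1] + t * u[1])
    dy <- pts[, 2] - (P0[2] + t * u[2])
    dz <- pts[, 3] - (P0[3] + t * u[3])
    list(dist = sqrt(dx^2 + dy^2 + dz^2), s = s0 + t,
         tangent = matrix(u, n, 3, byrow = TRUE))
  }

  cand <- list(
    seg_closest(o, c(0, 0, 1), La, 0),
    local({
      thp <- atan2(pts[, 3] - C[3], pts[, 1] - C[1])
      thc <- ifelse(thp < -pi / 2, pi, pmin(pmax(thp, 0), pi))
      qx <- C[1] + Ra * cos(thc); qy <- C[2]; qz <- C[3] + Ra * sin(thc)
      list(dist = sqrt((pts[, 1] - qx)^2 + (pts[, 2] - qy)^2 + (pts[, 3] - qz)^2),
           s = La + Ra * (pi - thc),
           tangent = cbind(sin(thc), 0, -cos(thc)))
    }),
    seg_closest(o + c(2 * Ra, 0, La), c(0, 0, -1), Ld, La + pi * Ra)
  )

  dist <- cand[[1]]$dist; s <- cand[[1]]$s; tangent <- cand[[1]]$tangent
  for (k in 2:3) {
    better <- cand[[k]]$dist < dist
    dist[better] <- cand[[k]]$dist[better]
    s[better] <- cand[[k]]$s[better]
    tangent[better, ] <- cand[[k]]$tangent[better, ]
  }
  list(dist = dist, s = s, tangent = tangent)
}
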