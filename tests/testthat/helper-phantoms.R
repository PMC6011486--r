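# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# Standard noiseless candy-cane flow phantom (true PWV 5 m/s).
std_phantom <- function() cached("std_phantom", make_flow_phantom(phantom_spec()))

# Seed points just inside the ends of a phantom's true centerline.
phantom_seeds <- function(ph, inset_mm = 5) {
  list(start = candy_cane_point(ph$geometry, inset_mm)$point[1, ],
       end = candy_cane_point(ph$geometry, ph$geometry$length - inset_mm)$point[1, ])
}

# Straight-tube velocity field along +z: radius r_mm, uniform (plug) or
# parabolic through-plane velocity v(t) given per phase. Cheap to build,
# used by waveform and plane tests.
straight_tube_field <- function(r_mm = 10, v_per_phase = c(0, 1),
                                profile = c("plug", "parabolic"),
                                spacing = c(1.4, 1.4, 2.5), len_mm = 100,
                                dt_ms = 20, venc = 1.5) {
  profile <- match.arg(profile)
  margin <- 8
  nx <- ceiling((2 * r_mm + 2 * margin) / spacing[1]) + 1
  ny <- ceiling((2 * r_mm + 2 * margin) / spacing[2]) + 1
  nz <- ceiling(len_mm / spacing[3]) + 1
  ax <- c((nx - 1) / 2 * spacing[1], (ny - 1) / 2 * spacing[2])
  ix <- (seq_len(nx) - 1) * spacing[1]
  iy <- (seq_len(ny) - 1) * spacing[2]
  rho2 <- outer((ix - ax[1])^2, (iy - ax[2])^2, `+`)
  prof2d <- switch(profile,
                   plug = (rho2 <= r_mm^2) * 1,
                   parabolic = ifelse(rho2 <= r_mm^2, 1 - rho2 / r_mm^2, 0))
  n_t <- length(v_per_phase)
  vz <- array(0, c(nx, ny, nz, n_t))
  for (k in seq_len(n_t))
    vz[, , , k] <- array(rep(prof2d * v_per_phase[k], nz), c(nx, ny, nz))
  zero <- array(0, c(nx, ny, nz, n_t))
  list(field = velocity_field(zero, zero, vz, spacing, dt_ms, venc),
       axis_xy = ax, r_mm = r_mm, len_mm = (nz - 1) * spacing[3],
       mask = lumen_mask(array(rho2 <= r_mm^2, c(nx, ny, nz)), spacing))
}

# Straight analytic centerline of exactly `length_mm` along +z.
straight_centerline <- function(length_mm = 300, step_mm = 1, origin = c(0, 0, 0)) {
  z <- seq(0, length_mm, by = step_mm)
  centerline(cbind(origin[1], origin[2], origin[3] + z))
}

# Simple synthetic single-pulse waveform object on a uniform grid.
toy_waveform <- function(q, dt_s = 0.02, s_mm = 0, id = 1L) {
  structure(list(plane_id = id, s_mm = s_mm,
                 t_s = (seq_along(q) - 1) * dt_s, q_ml_s = q),
            class = "flow_waveform")
}
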