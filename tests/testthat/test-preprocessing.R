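test_that("temporal unwrapping follows aliasing arithmetic and is idempotent", {
  # single-voxel field: stored -1.3 m/s whose temporal neighbour is 1.4
  mk <- function(v) {
    a <- array(0, c(2, 2, 2, 2))
    a[1, 1, 1, ] <- v
    a
  }
  f <- velocity_field(mk(c(1.4, -1.3)), mk(0), mk(0),
                      spacing = c(1, 1, 1), dt_ms = 20, venc = 1.5)
  u <- unwrap_velocity(f)
  expect_equal(u$vx[1, 1, 1, 2], -1.3 + 3.0)     # corrected to 1.7
  # wrap-free data are returned unchanged, and unwrapping is idempotent
  g <- velocity_field(mk(c(0.2, 0.4)), mk(0), mk(0), c(1, 1, 1), 20, 1.5)
  expect_identical(unwrap_velocity(g)$vx, g$vx)
  expect_identical(unwrap_velocity(u)$vx, u$vx)
})

test_that("unwrapping restores a wrapped noisy phantom inside the lumen", {
  spec <- phantom_spec(peak_velocity = 1.7, venc = 1.5, noise_sd = 0.02,
                       wrap_enabled = TRUE, seed = 2, n_phases = 12,
                       ascending_mm = 30, arch_radius_mm = 25,
                       descending_mm = 40)
  suppressWarnings({
    wrapped <- make_flow_phantom(spec)
    spec_t <- spec; spec_t$wrap_enabled <- FALSE
    truth <- make_flow_phantom(spec_t)
  })
  un <- unwrap_velocity(wrapped$field)
  lum <- rep(wrapped$lumen$mask, dim(un$vx)[4])
  for (comp in c("vx", "vy", "vz"))
    expect_lt(max(abs(un[[comp]][lum] - truth$field[[comp]][lum])), 5 * 0.02)
})

test_that("eddy-current correction recovers an injected first-order offset", {
  eddy <- list(c(0.05, 2e-4, 0, 0), c(0.01, 0, -1e-4, 0), c(-0.02, 0, 0, 1e-4))
  spec <- phantom_spec(eddy = eddy, n_phases = 6, ascending_mm = 30,
                       arch_radius_mm = 25, descending_mm = 40)
  suppressWarnings(ph <- make_flow_phantom(spec))
  static <- static_tissue_mask(ph$lumen, 2)
  corr <- correct_eddy_currents(ph$field, static)
  fit <- attr(corr, "eddy_fit")
  expect_equal(fit$vx, eddy[[1]], tolerance = 0.05)
  expect_equal(fit$vy[c(1, 3)], eddy[[2]][c(1, 3)], tolerance = 0.05)
  expect_equal(fit$vz[c(1, 4)], eddy[[3]][c(1, 4)], tolerance = 0.05)
  # post-correction static temporal-mean velocity is zero-mean
  tm <- rowMeans(matrix(corr$vx, length(static), dim(corr$vx)[4]))
  expect_lt(abs(mean(tm[static])), 1e-10)
})

test_that("eddy correction is linear and the identity on clean data", {
  base <- phantom_spec(n_phases = 4, ascending_mm = 30, arch_radius_mm = 25,
                       descending_mm = 40)
  e1 <- list(c(0.05, 0, 0, 0), c(0, 0, 0, 0), c(0, 0, 0, 0))
  e2 <- list(c(0, 2e-4, 0, 0), c(0, 0, 0, 0), c(0.03, 0, 0, 0))
  mk <- function(eddy) {
    s <- base; s$eddy <- eddy
    suppressWarnings(make_flow_phantom(s))
  }
  ph0 <- mk(NULL); ph1 <- mk(e1); ph2 <- mk(e2)
  ph12 <- mk(Map(`+`, e1, e2))
  static <- static_tissue_mask(ph0$lumen, 2)
  c0 <- correct_eddy_currents(ph0$field, static)
  c12 <- correct_eddy_currents(ph12$field, static)
  f1 <- attr(correct_eddy_currents(ph1$field, static), "eddy_fit")
  f2 <- attr(correct_eddy_currents(ph2$field, static), "eddy_fit")
  f12 <- attr(c12, "eddy_fit")
  for (comp in c("vx", "vy", "vz")) {
    # fitted coefficients add
    expect_equal(f12[[comp]], f1[[comp]] + f2[[comp]] -
                   attr(c0, "eddy_fit")[[comp]], tolerance = 1e-8)
    # zero injected offset, zero noise: field unchanged to tolerance
    expect_lt(max(abs(c0[[comp]] - ph0$field[[comp]])), 1e-6)
  }
  expect_error(correct_eddy_currents(ph0$field,
                                     array(FALSE, dim(ph0$field$vx)[1:3])),
               "static mask")
})

test_that("lumen segmentation matches phantom truth and behaves monotonically", {
  ph <- std_phantom()
  seg <- segment_lumen(ph$field, 0.2)
  dice <- 2 * sum(seg$mask & ph$lumen$mask) /
    (sum(seg$mask) + sum(ph$lumen$mask))
  expect_gte(dice, 0.90)
  # deterministic
  expect_identical(segment_lumen(ph$field, 0.2)$mask, seg$mask)
  # monotone in threshold: higher fraction never grows the mask
  seg5 <- segment_lumen(ph$field, 0.5, closing_iter = 0)
  seg2 <- segment_lumen(ph$field, 0.2, closing_iter = 0)
  expect_true(all(seg2$mask[seg5$mask]))
  # threshold above the maximum speed yields an empty segmentation
  expect_error(segment_lumen(ph$field, 1.0), "empty")
})
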