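test_that("flow integration matches area times velocity", {
  # plug flow 1 m/s through a 10 mm tube: Q = pi * 100 mm^2 * 1 m/s
  tube <- straight_tube_field(r_mm = 10, v_per_phase = c(0, 1))
  cl <- straight_centerline(tube$len_mm, origin = c(tube$axis_xy, 0))
  pl <- place_planes(cl, tube$mask, spacing_mm = 40, s_start = 20,
                     s_end = tube$len_mm - 20)[[1]]
  w <- extract_flow_waveform(tube$field, pl)
  expect_equal(w$q_ml_s[2], pi * 100, tolerance = 0.03)
  expect_equal(w$q_ml_s[1], 0)
  # parabolic profile with peak v_max: Q = A * v_max / 2
  par <- straight_tube_field(r_mm = 10, v_per_phase = c(0, 1),
                             profile = "parabolic")
  wp <- extract_flow_waveform(par$field, pl)
  expect_equal(wp$q_ml_s[2], pi * 100 / 2, tolerance = 0.03)
  # zero velocity field: Q identically zero
  zero <- straight_tube_field(r_mm = 10, v_per_phase = c(0, 0))
  expect_equal(extract_flow_waveform(zero$field, pl)$q_ml_s, c(0, 0))
})

test_that("time-to-foot finds the onset of a noiseless ramp", {
  # baseline 0 until t = 0.100 s, then a linear ramp
  t <- (0:14) * 0.02
  q <- pmax(0, (t - 0.100) * 1000)
  expect_equal(arrival_time_ttf(toy_waveform(q)), 0.100, tolerance = 1e-9)
  # flat waveform is rejected
  expect_error(arrival_time_ttf(toy_waveform(rep(1, 10))), "flat")
  expect_error(arrival_time_half_peak(toy_waveform(rep(0, 10))), "flat")
})

test_that("half-peak crossing is located by linear interpolation", {
  # triangle pulse: baseline 0, peak 100 reached linearly from t=0.1 to 0.2
  t <- (0:14) * 0.02
  q <- approx(c(0, 0.1, 0.2, 0.3), c(0, 0, 100, 0), xout = t, rule = 2)$y
  expect_equal(arrival_time_half_peak(toy_waveform(q)), 0.150, tolerance = 1e-9)
})

test_that("arrival detectors are equivariant under a time shift", {
  spec <- phantom_spec()
  t <- (0:24) * 0.02
  q <- 300 * pulse_waveform(t, 0.08, 0.08, 0.12, 1)
  shift_k <- 3                                    # 60 ms, within diastole
  qs <- c(rep(0, shift_k), q[1:(length(q) - shift_k)])
  dt <- shift_k * 0.02
  expect_equal(arrival_time_ttf(toy_waveform(qs)),
               arrival_time_ttf(toy_waveform(q)) + dt, tolerance = 1e-6)
  expect_equal(arrival_time_half_peak(toy_waveform(qs)),
               arrival_time_half_peak(toy_waveform(q)) + dt, tolerance = 1e-6)
})

test_that("cross-correlation lag is exact on identity and antisymmetric", {
  t <- (0:24) * 0.02
  q <- 300 * pulse_waveform(t, 0.08, 0.08, 0.12, 1)
  w <- toy_waveform(q)
  expect_lt(abs(arrival_shift_xcor(w, w)), 1e-3)
  # a known 12 ms shift on the 20 ms grid, generated analytically
  q12 <- 300 * pulse_waveform(t - 0.012, 0.08, 0.08, 0.12, 1)
  w12 <- toy_waveform(q12)
  expect_equal(arrival_shift_xcor(w12, w), 0.012, tolerance = 0.002)
  expect_equal(arrival_shift_xcor(w, w12), -arrival_shift_xcor(w12, w),
               tolerance = 0.002)
  expect_error(arrival_shift_xcor(toy_waveform(rep(1, 25)), w), "constant")
})

test_that("PWV is the inverse slope of the arrival-time fit", {
  s <- seq(0, 300, by = 5)
  arr <- structure(data.frame(s_mm = s, tau_s = s / 5000),
                   method = "ttf", class = c("arrival_times", "data.frame"))
  est <- suppressWarnings(fit_pwv(arr))
  expect_equal(est$pwv, 5.000, tolerance = 1e-9)
  expect_equal(est$r_squared, 1, tolerance = 1e-12)
  expect_equal(est$pwv, 1 / (est$slope_s_per_mm * 1000))
  # constant arrival times: zero slope, flagged invalid
  flat <- data.frame(s_mm = s, tau_s = 0.1)
  flat_est <- suppressWarnings(fit_pwv(flat))
  expect_false(flat_est$valid)
  expect_true(is.na(flat_est$pwv))
})

test_that("arrival times and PWV are invariant to flow-rate scaling", {
  ph <- std_phantom()
  lum <- segment_lumen(ph$field, 0.2)
  cl <- extract_centerline(lum, candy_cane_point(ph$geometry, 5)$point[1, ],
                           candy_cane_point(ph$geometry,
                                            ph$geometry$length - 5)$point[1, ])
  planes <- place_planes(cl, lum, spacing_mm = 30, s_start = 20,
                         s_end = cl$length - 20)
  wfs <- lapply(planes, extract_flow_waveform, field = ph$field)
  # batched extraction agrees with per-plane extraction
  wfs_batch <- extract_flow_waveforms(ph$field, planes)
  for (i in seq_along(wfs))
    expect_equal(wfs_batch[[i]]$q_ml_s, wfs[[i]]$q_ml_s, tolerance = 1e-12)
  wfs_scaled <- lapply(wfs, function(w) { w$q_ml_s <- 7.3 * w$q_ml_s; w })
  for (m in c("ttf", "half_peak", "xcor")) {
    a <- arrival_times(wfs, m)
    b <- arrival_times(wfs_scaled, m)
    expect_equal(b$tau_s, a$tau_s, tolerance = 1e-9)
    expect_equal(fit_pwv(b)$pwv, fit_pwv(a)$pwv, tolerance = 1e-9)
  }
})

test_that("halving the temporal resolution changes noiseless PWV by < 1%", {
  est20 <- cached("pwv_dt20", {
    ph <- std_phantom()
    g <- ph$geometry
    estimate_pwv(ph$field, candy_cane_point(g, 5)$point[1, ],
                 candy_cane_point(g, g$length - 5)$point[1, ],
                 spacing_mm = 15)
  })
  est10 <- cached("pwv_dt10", {
    ph <- make_flow_phantom(phantom_spec(dt_ms = 10, n_phases = 40))
    g <- ph$geometry
    estimate_pwv(ph$field, candy_cane_point(g, 5)$point[1, ],
                 candy_cane_point(g, g$length - 5)$point[1, ],
                 spacing_mm = 15)
  })
  for (m in c("ttf", "half_peak", "xcor"))
    expect_equal(est10[[m]]$pwv, est20[[m]]$pwv, tolerance = 0.01)
})
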