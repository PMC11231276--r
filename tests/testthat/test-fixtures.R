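test_that("radius profile hits the requested stenosis exactly at the throat", {
  flat <- make_radius_profile(beta_target = 0)
  expect_true(all(flat$r == flat$r[1]))
  pr <- make_radius_profile(r0 = 1.5, beta_target = 45)
  expect_equal(min(pr$r), 1.5 * 0.55, tolerance = 1e-12)
  expect_equal(pr$s[which.min(pr$r)], pr$truth$c)
  expect_error(make_radius_profile(beta_target = 100), "closes the lumen")
  expect_error(make_radius_profile(c = 40, L = 30), "0 < c < L")
})

test_that("beta computed from the generated profile recovers beta_target", {
  for (b in c(20, 32, 45)) {
    rep <- compute_beta_profile(as_diameter_profile(make_radius_profile(beta_target = b)))
    expect_lt(abs(rep$beta_max - b), 0.5)
  }
})

test_that("cine rendering follows the chord-attenuation model", {
  pr <- make_radius_profile()
  img0 <- imaging_params(A = 0)
  cine0 <- render_cine(pr, img0, seed = 1L)
  expect_true(all(vapply(cine0$frames, function(f)
    all(f == img0$I_bg), logical(1))))
  # noiseless on-centerline pixel: I = I_bg - 2*A*r*contrast (within rounding)
  img <- imaging_params()
  cine <- render_cine(pr, img, seed = 1L)
  ctr_row <- img$size[1] %/% 2
  col <- img$size[2] %/% 2 - 20L                 # away from the throat
  s_mm <- (col - cine$truth$x0_px) * img$mm_per_px
  r <- approx(pr$s, pr$r, xout = s_mm)$y
  expect_lt(abs(cine$frames[[cine$ed_frame]][ctr_row, col] -
                  (img$I_bg - 2 * img$A * r)), 1.0)
})

test_that("the end-diastolic frame is the darkest, for several seeds", {
  pr <- make_radius_profile()
  img <- imaging_params(noise_sd = 300)
  for (seed in 1:3) {
    cine <- render_cine(pr, img, n_frames = 10L, ed_frame = 4L, seed = seed)
    means <- vapply(cine$frames, mean, numeric(1))
    expect_identical(which.min(means), 4L)
  }
})

test_that("rendering is deterministic in the seed and validates geometry", {
  pr <- make_radius_profile()
  img <- imaging_params(noise_sd = 500)
  c1 <- render_cine(pr, img, seed = 7L)
  c2 <- render_cine(pr, img, seed = 7L)
  expect_identical(c1$frames, c2$frames)
  c3 <- render_cine(pr, img, seed = 8L)
  expect_false(identical(c1$frames, c3$frames))
  expect_error(render_cine(make_radius_profile(L = 60), img), "wider than image")
})

test_that("synthetic pressure waves honour mean, amplitude and periodicity", {
  flatw <- make_pressure_wave(pulse_amplitude = 0)
  expect_true(all(flatw$p == 75))
  w <- make_pressure_wave(mean = 82, pulse_amplitude = 37, T = 0.9)
  expect_lt(abs(mean(w$p) - 82) / 82, 1e-6)
  expect_equal(max(w$p) - min(w$p), 37, tolerance = 1e-9)
  # periodic wrap: interpolation at t = T returns the first sample
  expect_equal(vffr:::wave_interp(w$t, w$p, w$period, w$period), w$p[1])
  expect_error(make_pressure_wave(mean = 5, pulse_amplitude = 40),
               "negative pressures")
})

test_that("distal traces behave like the Windkessel they came from", {
  wk <- wk3_params(0.26, 117.5, 0.0032)
  Qc <- make_flow_wave(mean = 0.64, pulse_amplitude = 0)
  tr <- make_distal_trace(Qc, wk)
  expect_lt(max(abs(tr$p - (wk$R1 + wk$R2) * 0.64)) / mean(tr$p), 1e-3)
  # sinusoidal flow: amplitude through |Z(omega)|
  T <- 0.8; n <- 256
  t <- seq(0, T, length.out = n + 1)[1:n]
  Qs <- flow_wave(t, 0.6 + 0.15 * sin(2 * pi * t / T), T)
  trs <- make_distal_trace(Qs, wk)
  Z <- wk$R1 + wk$R2 / (1 + 2i * pi / T * wk$R2 * wk$C)
  amp <- 2 * Mod(fft(trs$p)[2]) / length(trs$p)
  expect_lt(abs(amp - 0.15 * Mod(Z)) / (0.15 * Mod(Z)), 0.01)
  expect_error(make_distal_trace(Qs, wk3_params(0.2, 100, 0.003), T = 1.0),
               "periodic with period")
})

test_that("cines and waves round-trip through their file formats", {
  dir <- withr::local_tempdir()
  pr <- make_radius_profile()
  cine <- render_cine(pr, imaging_params(noise_sd = 200), n_frames = 4L,
                      ed_frame = 2L, seed = 5L)
  write_cine(cine, file.path(dir, "cine"))
  back <- read_cine(file.path(dir, "cine"))
  expect_equal(back$n_frames, 4L)
  expect_identical(back$ed_frame, 2L)
  expect_equal(back$frames[[3]], cine$frames[[3]], tolerance = 1e-12)
  w <- make_pressure_wave()
  write_wave_csv(w, file.path(dir, "w.csv"))
  w2 <- read_wave_csv(file.path(dir, "w.csv"))
  expect_equal(w2$p, w$p, tolerance = 1e-6)
  expect_equal(w2$period, w$period, tolerance = 1e-9)
  q <- make_flow_wave()
  write_wave_csv(q, file.path(dir, "q.csv"))
  expect_s3_class(read_wave_csv(file.path(dir, "q.csv")), "flow_wave")
})
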