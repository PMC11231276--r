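ref_wk <- function(i) {
  r <- cohort_reference()
  wk3_params(r$R1[i], r$R2[i], r$C[i])
}

test_that("Hagen-Poiseuille outlet law is linear", {
  expect_equal(poiseuille_dp(2, 3), 6)
  expect_equal(poiseuille_dp(2, 0), 0)
  expect_equal(poiseuille_dp(5, 2 * 1.7), 2 * poiseuille_dp(5, 1.7))
  expect_error(poiseuille_dp(-1, 1), "R must be > 0")
})

test_that("wk3_solve reproduces the steady state and the analytic decay", {
  wk <- wk3_params(0.25, 100, 0.003)
  Qc <- make_flow_wave(mean = 0.7, pulse_amplitude = 0, T = 0.8)
  pw <- wk3_solve(Qc, wk)
  expect_lt(max(abs(pw$p - (0.25 + 100) * 0.7)) / ((0.25 + 100) * 0.7), 1e-3)
  # free decay: Q = 0, P(t) = P0 exp(-t/(R2 C)); check at t = R2*C
  wk2 <- wk3_params(0.2, 1, 0.3)           # tau = 0.3 s
  tau <- wk2$R2 * wk2$C
  Q0 <- flow_wave(seq(0, 0.6, length.out = 65)[1:64], rep(0, 64), 0.6)
  dt <- 0.6 / 600
  dec <- wk3_solve(Q0, wk2, dt = dt, p_init = 80, n_periods = 1L)
  p_tau <- dec$p[which.min(abs(dec$t - tau))]
  expect_lt(abs(p_tau - 80 * exp(-1)) / (80 * exp(-1)), 0.005)
})

test_that("wk3_solve matches the impedance transfer function for a sinusoid", {
  wk <- ref_wk(1)
  T <- 0.8; n <- 256
  t <- seq(0, T, length.out = n + 1)[1:n]
  for (harm in c(1, 3)) {
    w <- 2 * pi * harm / T
    Q <- flow_wave(t, 0.7 + 0.2 * sin(w * t), T)
    pw <- wk3_solve(Q, wk, dt = T / 1600, n_periods = 60L)
    Z <- wk$R1 + wk$R2 / (1 + 1i * w * wk$R2 * wk$C)
    # complex amplitude of the response at that harmonic via FFT
    ph <- fft(pw$p)[harm + 1] / length(pw$p)
    amp <- 2 * Mod(ph)
    expect_lt(abs(amp - 0.2 * Mod(Z)) / (0.2 * Mod(Z)), 0.01)
    # mean maps through the DC impedance
    expect_lt(abs(mean(pw$p) - (wk$R1 + wk$R2) * 0.7) / mean(pw$p), 0.01)
  }
})

test_that("wk3_solve reaches a periodic state (consecutive periods agree)", {
  wk <- ref_wk(2)
  Q <- make_flow_wave(mean = 0.8, pulse_amplitude = 0.7)
  p1 <- wk3_solve(Q, wk, n_periods = 40L)
  p2 <- wk3_solve(Q, wk, n_periods = 41L)
  expect_lt(sqrt(mean((p1$p - p2$p)^2)), 1e-6 * mean(p1$p))
})

test_that("wk3_fit recovers ground-truth parameters from a noiseless trace", {
  wk <- ref_wk(3)
  Q <- make_flow_wave(mean = 0.55, pulse_amplitude = 0.5)
  trace <- make_distal_trace(Q, wk)
  fit <- wk3_fit(trace, Q)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$R1 - wk$R1) / wk$R1, 1e-3)
  expect_lt(abs(fit$params$R2 - wk$R2) / wk$R2, 1e-3)
  expect_lt(abs(fit$params$C - wk$C) / wk$C, 1e-3)
})

test_that("wk3_fit recovers parameters from noisy multi-beat recordings", {
  # Recovery simulation at 2% multiplicative noise: a 4-beat recording is
  # ensemble-averaged (the clinical practice, and the package's FFT
  # averaging) before fitting.  The ground-truth set has a characteristic
  # impedance at 2% of total resistance, the textbook identifiable regime;
  # see the methods vignette for why a sub-percent R1 fraction cannot be
  # resolved at this noise level.
  wk <- wk3_params(2, 100, 0.003)
  Q <- sharp_flow_wave()
  errs <- sapply(1:20, function(seed) {
    beats <- lapply(1:4, function(b)
      make_distal_trace(Q, wk, dt = Q$period / 1000, noise_sd = 0.02,
                        seed = 1000L * seed + b))
    f <- wk3_fit(average_waves_fft(beats), Q)
    max(abs(f$params$R1 - wk$R1) / wk$R1,
        abs(f$params$R2 - wk$R2) / wk$R2,
        abs(f$params$C - wk$C) / wk$C)
  })
  expect_lt(median(errs), 0.05)
})

test_that("wk3_fit flags the structurally unidentifiable constant-flow case", {
  t <- seq(0, 0.8, length.out = 65)[1:64]
  Q <- flow_wave(t, rep(0.6, 64), 0.8)
  P <- pressure_wave(t, rep(70, 64), 0.8)
  expect_warning(fit <- wk3_fit(P, Q), "unidentifiable")
  expect_true(fit$degenerate)
  expect_equal(fit$params$R1 + fit$params$R2, 70 / 0.6, tolerance = 1e-10)
})

test_that("fit is invariant to a joint rescaling of flow and pressure", {
  wk <- ref_wk(4)
  Q <- make_flow_wave(mean = 0.62, pulse_amplitude = 0.5)
  tr <- make_distal_trace(Q, wk)
  f1 <- wk3_fit(tr, Q)
  k <- 2.5
  Qk <- flow_wave(Q$t, k * Q$q, Q$period)
  trk <- pressure_wave(tr$t, k * tr$p, tr$period)
  f2 <- wk3_fit(trk, Qk)
  expect_equal(f2$params$R1, f1$params$R1, tolerance = 1e-6)
  expect_equal(f2$params$R2, f1$params$R2, tolerance = 1e-6)
  expect_equal(f2$params$C, f1$params$C, tolerance = 1e-6)
})

test_that("cohort averaging reproduces the published mean parameter set", {
  avg <- average_wk3(lapply(1:5, ref_wk))
  expect_equal(avg$R1, 0.2622364, tolerance = 1e-12)
  expect_equal(avg$R2, 117.554746, tolerance = 1e-12)
  expect_equal(avg$C, 0.003236, tolerance = 1e-12)
})

test_that("averaging is permutation-invariant and idempotent", {
  ps <- lapply(1:5, ref_wk)
  a1 <- average_wk3(ps)
  a2 <- average_wk3(ps[c(3, 1, 5, 2, 4)])
  expect_identical(unclass(a1), unclass(a2))
  same <- average_wk3(list(ps[[2]], ps[[2]], ps[[2]]))
  expect_equal(unclass(same), unclass(ps[[2]]), tolerance = 1e-15)
})

test_that("parameter error report uses truncation toward zero (published rows)", {
  avg <- average_wk3(lapply(1:5, ref_wk))
  expect_identical(wk3_error_report(ref_wk(4), avg)[["R1"]], 147L)
  expect_identical(wk3_error_report(ref_wk(3), avg)[["C"]], 26L)
  expect_identical(wk3_error_report(ref_wk(2), avg)[["R2"]], 54L)
  expect_identical(unname(wk3_error_report(avg, avg)), c(0L, 0L, 0L))
})

test_that("FFT ensemble averaging equals the time-domain mean", {
  waves <- lapply(1:4, function(i)
    make_pressure_wave(mean = 70 + 3 * i, pulse_amplitude = 30 + 2 * i))
  avg <- average_waves_fft(waves)
  direct <- rowMeans(sapply(waves, `[[`, "p"))
  expect_lt(max(abs(avg$p - direct)) / max(abs(direct)), 1e-10)
  expect_equal(mean(avg$p), mean(sapply(waves, function(w) mean(w$p))),
               tolerance = 1e-12)
  # n copies of one wave reproduce that wave
  same <- average_waves_fft(list(waves[[1]], waves[[1]], waves[[1]]))
  expect_equal(same$p, waves[[1]]$p, tolerance = 1e-12)
  # unequal lengths are resampled to the finest grid
  w2 <- wave_resample(waves[[2]], 128L)
  mixed <- average_waves_fft(list(waves[[1]], w2))
  expect_length(mixed$p, 256L)
  expect_error(average_waves_fft(list()), "empty")
  # optional anchoring of the averaged mean to a reference patient
  anch <- average_waves_fft(waves, scale_to = waves[[1]])
  expect_equal(mean(anch$p), mean(waves[[1]]$p), tolerance = 1e-12)
  expect_equal(mean(average_waves_fft(waves, scale_to = 80)$p), 80,
               tolerance = 1e-12)
})

test_that("the relaxed Windkessel sub-iteration has the right limits", {
  # C -> 0: the implicit target collapses to (R1+R2)*Q
  wk <- wk3_params(0.3, 100, 1e-12)
  st <- list(p_prev = 60, q_prev = 0.5, q_now = 0.7, p_guess = 60)
  out <- couple_wk3_outlet(st, wk, dt = 0.005, relax = 1)
  expect_equal(out$target, (0.3 + 100) * 0.7, tolerance = 1e-6)
  # convergence flag fires when the update is below 1e-3 mmHg
  st2 <- list(p_prev = out$p, q_prev = 0.7, q_now = 0.7, p_guess = out$p)
  expect_true(couple_wk3_outlet(st2, wk, dt = 0.005)$converged)
})
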