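test_that("boundary-condition specs are validated against the method table", {
  w <- make_pressure_wave()
  wk <- wk3_params(0.26, 117, 0.0032)
  b1 <- assemble_bc(1L, 75, list(R = 118))
  expect_identical(b1$outlet$p_ref, 0)
  expect_identical(b1$wall, "rigid-no-slip")
  b3 <- assemble_bc(3L, w, wk)
  expect_match(b3$tag, "average")
  expect_s3_class(assemble_bc(4L, w, make_pressure_wave(mean = 70)), "bc_spec")
  expect_error(assemble_bc(5L, w, wk), "1, 2, 3 or 4")
  expect_error(assemble_bc(2L, w, list(R = 1)), "wk3_params")
  expect_error(assemble_bc(1L, w, list(R = 1)), "constant inlet")
  expect_error(assemble_bc(4L, w, make_pressure_wave(T = 1.0)), "period")
})

test_that("steady Newtonian tube flow approximates Hagen-Poiseuille", {
  fld <- solve_tube(dp_pa = 100)            # 60 x 15 cells
  Q_an <- pi * (1.5e-3)^4 * 100 / (8 * 0.0035 * 0.03)
  expect_lt(abs(fld$q_in - Q_an) / Q_an, 0.03)
  expect_lt(abs(fld$q_in - fld$q_out) / fld$q_in, 0.005)   # mass balance
  expect_true(fld$converged)
})

test_that("equal inlet and outlet reference pressures give zero flow", {
  g <- straight_tube_grid(20L, 4L)
  bc <- assemble_bc(1L, 75, list(R = 50, p_ref = 75))
  fld <- solve_steady(g, newtonian_blood(), bc, sim_config())
  expect_lt(abs(fld$q_in), 1e-12)
  p_rng <- diff(range(fld$p))
  expect_lt(p_rng, 1e-6 * 75 * 133.322)     # uniform pressure field
})

test_that("a very large outlet resistance throttles the flow to near zero", {
  g <- straight_tube_grid(20L, 4L)
  base <- solve_steady(g, newtonian_blood(),
                       assemble_bc(1L, 75, list(R = 118, p_ref = 0)),
                       sim_config())
  throttled <- solve_steady(g, newtonian_blood(),
                            assemble_bc(1L, 75, list(R = 118 * 200, p_ref = 0)),
                            sim_config())
  expect_lt(throttled$q_in, base$q_in / 100)
})

test_that("steady solves are bitwise deterministic", {
  f1 <- solve_tube(n_axial = 24L, n_radial_core = 4L)
  f2 <- solve_tube(n_axial = 24L, n_radial_core = 4L)
  expect_identical(f1$residuals, f2$residuals)
  expect_identical(f1$p, f2$p)
})

test_that("a constant 'transient' drive converges to the steady solution", {
  g <- straight_tube_grid(40L, 6L)
  pin <- 75; pout <- 73.5
  wconst_in <- make_pressure_wave(mean = pin, pulse_amplitude = 0)
  wconst_out <- make_pressure_wave(mean = pout, pulse_amplitude = 0)
  # tight residual tolerance: the transient residual norm carries the large
  # time-derivative history terms in its denominator, so 1e-6 here matches
  # the steady solve's effective 1e-5
  hist <- suppressWarnings(solve_transient(g, newtonian_blood(),
                                           assemble_bc(4L, wconst_in, wconst_out),
                                           sim_config(n_cycles = 2L, tol = 1e-6)))
  q_trans <- mean(tail(hist$q_in, 20))
  stdy <- solve_steady(g, newtonian_blood(),
                       assemble_bc(1L, pin, list(R = 1e-6, p_ref = pout)),
                       sim_config(tol = 1e-6))
  expect_lt(abs(q_trans - stdy$q_in) / stdy$q_in, 0.005)
  dp_trans <- mean(tail(hist$p_in, 20)) - mean(tail(hist$p_out, 20))
  dp_stdy <- (pin - pout) * 133.322
  expect_lt(abs(dp_trans - dp_stdy) / dp_stdy, 0.005)
  # instantaneous incompressible mass balance at every stored step
  expect_lt(max(abs(hist$q_in - hist$q_out)) / max(abs(hist$q_in)), 0.005)
})

test_that("time discretisation converges at second order (Richardson)", {
  g <- straight_tube_grid(24L, 5L)
  win <- make_pressure_wave(mean = 75, pulse_amplitude = 8, n_harmonics = 2L)
  wout <- make_pressure_wave(mean = 73.5, pulse_amplitude = 0)
  # observable: first-harmonic complex amplitude of the final-cycle inlet
  # flow, phase-aligned to t = 0 (samples are stored at t = dt, 2dt, ...)
  h1 <- vapply(c(0.02, 0.01, 0.005), function(dt) {
    h <- suppressWarnings(
      solve_transient(g, newtonian_blood(), assemble_bc(4L, win, wout),
                      sim_config(dt = dt, n_cycles = 3L, tol = 1e-6)))
    q <- tail(h$q_in, h$steps_per_cycle)
    n <- length(q)
    (fft(q)[2] / n) * exp(-2i * pi / n)
  }, complex(1))
  e1 <- Mod(h1[1] - h1[2]); e2 <- Mod(h1[2] - h1[3])
  expect_gt(e1 / e2, 2.5)                   # ~4 expected for 2nd order
})

test_that("the Windkessel-coupled run reaches a periodic state with closed sub-iterations", {
  prof <- as_diameter_profile(make_radius_profile(beta_target = 32))
  g <- build_grid(prof, n_axial = 30L, n_radial_core = 4L)
  wk <- wk3_params(0.26, 117.5, 0.0032)
  bc <- assemble_bc(2L, make_pressure_wave(), wk)
  hist <- solve_transient(g, rheology_params(), bc, sim_config())
  expect_true(hist$converged)
  expect_true(all(hist$wk_subconverged))
  expect_lt(hist$cycle_change, 0.01)
  expect_true(all(hist$res_final <= 1e-5 + 1e-12))
  # replaying the recorded outlet flow through the standalone 0D integrator
  # reproduces the coupled outlet pressure
  n <- hist$steps_per_cycle
  Q <- flow_wave((seq_len(n) - 1) * hist$dt, tail(hist$q_out, n) / 1e-6,
                 hist$period)
  pw <- wk3_solve(Q, wk, dt = hist$period / n)
  p_solver <- tail(hist$p_out, n) / 133.322
  expect_lt(max(abs(pw$p - p_solver)) / mean(p_solver), 0.005)
})

test_that("no-slip holds at the wall and the parabola emerges mid-tube", {
  fld <- solve_tube(dp_pa = 100, n_axial = 40L, n_radial_core = 10L)
  i <- 20L
  rc <- fld$rc[i, ]; uz <- fld$uz[i, ]
  R <- 1.5e-3
  u_an <- (100 / 0.03) * (R^2 - rc^2) / (4 * 0.0035)
  expect_lt(sqrt(sum((uz - u_an)^2) / sum(u_an^2)), 0.04)
  # wall-adjacent velocity is a small fraction of the peak (no-slip wall)
  expect_lt(abs(uz[length(uz)]), 0.08 * max(uz))
})
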