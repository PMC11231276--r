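test_that("beta profile: uniform tube, exact ratio, and the guarded window", {
  s <- seq(0, 30, by = 0.1)
  uni <- structure(list(s_mm = s, d_mm = rep(3, length(s)), mm_per_px = NA),
                   class = "diameter_profile")
  expect_true(all(compute_beta_profile(uni)$beta == 0))
  # d = 0.55 D at the throat -> beta_max = 45 (the published beta convention)
  d <- rep(3, length(s)); d[150:152] <- 0.55 * 3    # flat-bottomed throat
  dip <- structure(list(s_mm = s, d_mm = d, mm_per_px = NA),
                   class = "diameter_profile")
  rep45 <- compute_beta_profile(dip)
  expect_equal(rep45$beta_max, 45, tolerance = 1e-9)
  expect_equal(rep45$s_min, s[150])               # proximal tie-break
  # throat too close to the inlet: no proximal reference window
  d2 <- rep(3, length(s)); d2[s <= 3] <- 1.5
  expect_error(compute_beta_profile(
    structure(list(s_mm = s, d_mm = d2, mm_per_px = NA),
              class = "diameter_profile")), "upstream window")
})

test_that("beta recovery from the generator and scale invariance", {
  pr <- as_diameter_profile(make_radius_profile(beta_target = 32))
  expect_lt(abs(compute_beta_profile(pr)$beta_max - 32), 0.5)
  scaled <- pr; scaled$d_mm <- 3.7 * pr$d_mm
  expect_equal(compute_beta_profile(scaled)$beta,
               compute_beta_profile(pr)$beta, tolerance = 1e-12)
})

test_that("diameter trend: exact line, constant, and sampling distribution", {
  s <- seq(0, 25, by = 0.25)
  line <- structure(list(s_mm = s, d_mm = 3.2 - 0.02 * s, mm_per_px = NA),
                    class = "diameter_profile")
  tr <- fit_diameter_trend(line)
  expect_equal(tr[["slope"]], -0.02, tolerance = 1e-12)
  expect_equal(tr[["intercept"]], 3.2, tolerance = 1e-12)
  flat <- line; flat$d_mm <- rep(2.8, length(s))
  expect_equal(fit_diameter_trend(flat)[["slope"]], 0, tolerance = 1e-12)
  # noisy taper: OLS slope lands within 3 theoretical sd essentially always
  sd_noise <- 0.05
  se <- sd_noise / sqrt(sum((s - mean(s))^2))
  hits <- with_seed_test(100L, function() {
    noisy <- line; noisy$d_mm <- line$d_mm + rnorm(length(s), sd = sd_noise)
    abs(fit_diameter_trend(noisy)[["slope"]] + 0.02) <= 3 * se
  })
  expect_gte(sum(hits), 97L)
})

test_that("revolved surface converges to the analytic lateral area", {
  s <- seq(0, 20, by = 0.05)
  cyl <- structure(list(s_mm = s, d_mm = rep(3, length(s)), mm_per_px = NA),
                   class = "diameter_profile")
  exact <- 2 * pi * 1.5 * 20
  err <- vapply(c(8L, 16L, 64L), function(nt)
    abs(surface_area(revolve_surface(cyl, nt)) - exact) / exact, numeric(1))
  expect_true(all(diff(err) < 0))                 # refinement reduces error
  expect_lt(err[3], 0.005)
  surf <- revolve_surface(cyl, 8L)
  rad <- sqrt(surf$vertices[, 2]^2 + surf$vertices[, 3]^2)
  expect_equal(rad, rep(1.5, nrow(surf$vertices)), tolerance = 1e-12)
  # axial silhouette is independent of the circumferential resolution
  expect_identical(revolve_surface(cyl, 8L)$r_mm, revolve_surface(cyl, 64L)$r_mm)
})

test_that("grid layer arithmetic is exact and reproducible", {
  prof <- as_diameter_profile(make_radius_profile(beta_target = 30))
  g <- build_grid(prof, n_axial = 40L, n_radial_core = 6L)
  expect_identical(g$n_cells, 40L * (6L + 7L))
  # wall-adjacent spacings form the geometric sequence and close exactly
  for (i in c(1L, 21L, 41L)) {
    rr <- g$R[i, ]
    dr <- diff(rr)
    lay <- tail(dr, 7)
    expect_equal(lay[-7] / lay[-1], rep(1.1, 6), tolerance = 1e-9)
    expect_equal(rr[length(rr)], g$r_wall[i], tolerance = 1e-12)
    expect_equal(sum(dr), g$r_wall[i], tolerance = 1e-12)
  }
  expect_identical(build_grid(prof, n_axial = 40L, n_radial_core = 6L)$R, g$R)
  expect_error(build_grid(prof, n_axial = 40L, n_radial_core = 6L,
                          bl_fraction = 1.2), "local radius")
})

test_that("axial clustering concentrates cells near the throat", {
  prof <- as_diameter_profile(make_radius_profile(beta_target = 40))
  g <- build_grid(prof, n_axial = 60L, n_radial_core = 5L,
                  refine_near_stenosis = TRUE)
  s0 <- 15
  ds <- diff(g$s_nodes)
  mid <- (g$s_nodes[-1] + g$s_nodes[-length(g$s_nodes)]) / 2
  near <- abs(mid - s0) < 0.2 * 30
  expect_lt(mean(ds[near]), mean(ds))
  guni <- build_grid(prof, n_axial = 60L, n_radial_core = 5L,
                     refine_near_stenosis = FALSE)
  expect_equal(max(abs(diff(guni$s_nodes) - 30 / 60)), 0, tolerance = 1e-9)
})

test_that("convergence report has one fewer difference than levels and 0% for identical levels", {
  prof <- as_diameter_profile(make_radius_profile(beta_target = 32))
  g <- build_grid(prof, n_axial = 24L, n_radial_core = 4L)
  bc <- assemble_bc(1L, 75, list(R = 118, p_ref = 0))
  case <- list(profile = prof, rheology = rheology_params(), bc = bc,
               cfg = sim_config(), stenosis = compute_beta_profile(prof))
  rep <- convergence_study(case, list(g, g))
  expect_length(rep$diff_pct, 1L)
  expect_equal(rep$diff_pct, 0, tolerance = 1e-9)
})
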