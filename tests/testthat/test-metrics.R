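# synthetic one-station WSS histories for the index identities
wss_row <- function(x) matrix(x, nrow = 1)

test_that("TAWSS: constant, sinusoid closed form, and shift invariance", {
  n <- 400; T <- 0.8
  t <- seq(0, T, length.out = n + 1)[1:n]
  expect_equal(tawss(wss_row(rep(1.7, n)), T), 1.7)
  s <- wss_row(2.3 * sin(2 * pi * t / T))
  expect_equal(tawss(s, T), 2 * 2.3 / pi, tolerance = 1e-4)
  shifted <- wss_row(2.3 * sin(2 * pi * (t + 0.19) / T))
  expect_equal(tawss(shifted, T), tawss(s, T), tolerance = 1e-6)
  expect_error(tawss(wss_row(1), NULL), "full cycle|cycle duration")
})

test_that("OSI: unidirectional zero, balanced reversal 0.5, bounded on random signals", {
  n <- 200; T <- 0.8
  uni <- wss_row(abs(rnorm(n)) + 0.1)
  expect_equal(as.numeric(osi(uni, T)), 0)
  sq <- wss_row(rep(c(1, -1), each = n / 2))
  expect_equal(as.numeric(osi(sq, T)), 0.5)
  set.seed(42)
  M <- matrix(rnorm(1000 * 50), 1000, 50)
  vals <- as.numeric(osi(M, T))
  expect_true(all(vals >= 0 & vals <= 0.5))
  z <- osi(wss_row(rep(0, n)), T)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "undefined"))
})

test_that("RRT follows its defining identity and flags degeneracies", {
  expect_equal(as.numeric(rrt(2, 0.25)), 1)
  expect_equal(as.numeric(rrt(3.1, 0)), 1 / 3.1)
  ta <- runif(20, 0.5, 4); os <- runif(20, 0, 0.49)
  expect_equal(as.numeric(rrt(ta, os)), 1 / ((1 - 2 * os) * ta), tolerance = 1e-12)
  expect_true(is.infinite(rrt(2, 0.5)))
  deg <- rrt(0, 0.2)
  expect_true(is.na(deg) && attr(deg, "undefined"))
})

test_that("HOLMES adopts the literature definition", {
  expect_equal(as.numeric(holmes(3, 0)), 1.5)
  expect_equal(as.numeric(holmes(3, 0.5)), 0)
  ta <- runif(10, 0.1, 2); os <- runif(10, 0, 0.5)
  expect_equal(as.numeric(holmes(ta, os)), ta * (0.5 - os), tolerance = 1e-12)
  expect_identical(attr(holmes(1, 0.1), "provenance"), "literature-definition")
})

test_that("wall shear stress matches the Poiseuille closed form and flips with the flow", {
  fld <- solve_tube(dp_pa = 100, n_axial = 60L, n_radial_core = 10L)
  ws <- wall_shear(fld)
  R <- 1.5e-3
  tau_an <- 4 * 0.0035 * fld$q_in / (pi * R^3)
  mid <- ws$s_mm > 5 & ws$s_mm < 25
  expect_lt(max(abs(ws$wss[mid, 1] - tau_an)) / tau_an, 0.03)
  # flow reversal flips the sign
  rev <- fld; rev$uz <- -fld$uz; rev$ur <- -fld$ur
  expect_equal(wall_shear(rev)$wss, -ws$wss, tolerance = 1e-12)
  # zero flow gives zero WSS
  g <- straight_tube_grid(20L, 4L)
  f0 <- solve_steady(g, newtonian_blood(),
                     assemble_bc(1L, 75, list(R = 50, p_ref = 75)), sim_config())
  expect_lt(max(abs(wall_shear(f0)$wss)), 1e-8)
})

test_that("FFR equals one for uniform pressure and zero flow", {
  g <- straight_tube_grid(20L, 4L)
  f0 <- solve_steady(g, newtonian_blood(),
                     assemble_bc(1L, 75, list(R = 50, p_ref = 75)), sim_config())
  res <- compute_ffr_steady(f0)
  expect_equal(res$ffr, 1, tolerance = 1e-9)
  expect_equal(res$Pd, res$Pa, tolerance = 1e-6)
})

test_that("the virtual wire is clipped into the domain, or errors beyond it", {
  prof <- as_diameter_profile(make_radius_profile(beta_target = 32))
  grid <- build_grid(prof, n_axial = 20L, n_radial_core = 4L)
  sten <- compute_beta_profile(prof)
  fake <- list(grid = grid, vol = matrix(1, 20, 11),
               p = array(rep(75 * 133.322, 20 * 11 * 4), c(20, 11, 4)))
  expect_warning(out <- compute_ffr(fake, sten, wire_offset = 20), "clipped")
  expect_lt(out$s_wire, 30)
  expect_equal(out$ffr, 1, tolerance = 1e-12)
})

test_that("the wall-metrics table reports all indices in clinical units", {
  n <- 100; T <- 0.8
  t <- seq(0, T, length.out = n + 1)[1:n]
  wssm <- rbind(1 + 0.5 * sin(2 * pi * t / T),   # unidirectional station
                0.2 * sin(2 * pi * t / T))       # perfectly reversing station
  ww <- structure(list(s_mm = c(1, 2), wss = wssm, t = t, period = T),
                  class = "wall_wss")
  wm <- wall_metrics(ww, include_holmes = TRUE)
  expect_named(wm, c("s_mm", "tawss_mmHg", "osi", "rrt_per_mmHg", "holmes_mmHg"))
  expect_equal(wm$osi[1], 0)
  expect_equal(wm$osi[2], 0.5, tolerance = 1e-9)
  expect_equal(wm$tawss_mmHg[1], 1 / 133.322, tolerance = 1e-3)
  expect_equal(wm$rrt_per_mmHg[1], 1 / wm$tawss_mmHg[1], tolerance = 1e-9)
  expect_true(is.infinite(wm$rrt_per_mmHg[2]))
  expect_equal(wm$holmes_mmHg[2], 0, tolerance = 1e-12)
})

test_that("FFR error reporting truncates toward zero (published rows)", {
  expect_equal(ffr_error(0.85, 0.87), 2.3)    # 2.3529 -> 2.3
  expect_equal(ffr_error(0.89, 0.93), 4.4)    # 4.4943 -> 4.4
  expect_equal(ffr_error(0.89, 0.885), 0.5)   # 0.5618 -> 0.5
  expect_equal(ffr_error(0.84, 0.869), 3.4)   # 3.4523 -> 3.4
  expect_equal(ffr_error(0.9, 0.9), 0)
  expect_error(ffr_error(1.2, 0.9), "\\(0, 1\\]")
})

test_that("pressure difference fields obey the algebraic identities", {
  a <- matrix(runif(60, 8000, 11000), 6, 10)
  fa <- structure(list(p = a), class = "flow_field")
  fb <- structure(list(p = 0.99 * a), class = "flow_field")
  expect_equal(pressure_diff_field(fa, fa), matrix(0, 6, 10))
  expect_equal(pressure_diff_field(fa, fb), matrix(1, 6, 10), tolerance = 1e-12)
  dab <- pressure_diff_field(fa, fb); dba <- pressure_diff_field(fb, fa)
  expect_equal(dab, -dba * fb$p / fa$p, tolerance = 1e-12)
  bad <- structure(list(p = a[1:3, ]), class = "flow_field")
  expect_error(pressure_diff_field(fa, bad), "different grids")
})
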