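test_that("normalisation is affine, bounded and rank-preserving", {
  pr <- make_radius_profile()
  cine <- render_cine(pr, imaging_params(noise_sd = 400), seed = 1L)
  ncine <- normalize_cine(cine)
  for (f in ncine$frames) expect_true(min(f) >= 0 && max(f) <= 1)
  expect_identical(order(as.vector(ncine$frames[[3]])),
                   order(as.vector(cine$frames[[3]])))
  # identical frames stay identical
  same <- cine
  same$frames <- rep(cine$frames[1], 4)
  nsame <- normalize_cine(same)
  expect_identical(nsame$frames[[1]], nsame$frames[[4]])
  # constant cine is rejected
  flat <- cine
  flat$frames <- lapply(1:3, function(i) matrix(100, 8, 8))
  expect_error(normalize_cine(flat), "zero dynamic range")
})

test_that("end-diastolic frame selection finds the opacified frame", {
  pr <- make_radius_profile()
  for (seed in 1:3) {
    cine <- normalize_cine(render_cine(pr, imaging_params(noise_sd = 300),
                                       n_frames = 9L, ed_frame = 7L, seed = seed))
    expect_identical(select_end_diastolic_frame(cine), 7L)
  }
  one <- render_cine(pr, imaging_params(), n_frames = 1L, ed_frame = 1L, seed = 1L)
  expect_identical(select_end_diastolic_frame(one), 1L)
  tie <- render_cine(pr, imaging_params(), n_frames = 4L, ed_frame = 2L, seed = 1L)
  tie$frames <- rep(tie$frames[1], 4)              # all identical: lowest index
  expect_identical(select_end_diastolic_frame(normalize_cine(tie)), 1L)
})

test_that("segmented lumen boundary lies within one pixel of the truth", {
  pr <- make_radius_profile(beta_target = 32)
  img <- imaging_params()
  cine <- normalize_cine(render_cine(pr, img, seed = 2L))
  mask <- segment_lumen(get_frame(cine))
  expect_false(mask$degenerate)
  tr <- cine$truth
  ctr_row <- img$size[1] / 2
  cols <- which(colSums(mask$mask) > 0)
  cols <- cols[5:(length(cols) - 5)]
  for (col in cols[seq(1, length(cols), by = 7)]) {
    s_mm <- (col - tr$x0_px) * img$mm_per_px
    r_px <- approx(pr$s, pr$r, xout = s_mm)$y / img$mm_per_px
    rows <- which(mask$mask[, col])
    # mask region boundary (pixel edge) vs the true lumen edge
    expect_lt(abs((min(rows) - 0.5) - (ctr_row - r_px)), 1.0)
    expect_lt(abs((max(rows) + 0.5) - (ctr_row + r_px)), 1.0)
  }
})

test_that("threshold edge cases: below-min errors, above-max flags degenerate", {
  pr <- make_radius_profile()
  cine <- normalize_cine(render_cine(pr, imaging_params(), seed = 1L))
  fr <- get_frame(cine)
  expect_error(segment_lumen(fr, list(method = "fixed", value = -0.1)),
               "no vessel found")
  deg <- segment_lumen(fr, list(method = "fixed", value = 1.1))
  expect_true(deg$degenerate)
  expect_true(all(deg$mask))
  # otsu override also segments the vessel
  mo <- segment_lumen(fr, list(method = "otsu"))
  expect_gt(sum(mo$mask), 100)
})

test_that("centerline of a straight band is its median row, with exact arclength", {
  band <- matrix(FALSE, 40, 60); band[18:24, 10:50] <- TRUE
  cl <- extract_centerline(band, mm_per_px = 0.1)
  expect_true(all(abs(cl$rc[, 1] - 21) < 1e-9))
  expect_true(all(diff(cl$s_mm) > 0))
  line <- matrix(FALSE, 20, 60); line[10, 5:55] <- TRUE
  cll <- extract_centerline(line, mm_per_px = 0.1)
  expect_equal(max(cll$s_mm), (51 - 1) * 0.1, tolerance = 1e-9)
})

test_that("curved-vessel centerline stays within a pixel of the truth", {
  pr <- make_radius_profile(beta_target = 0)
  img <- imaging_params()
  cine <- normalize_cine(render_cine(pr, img, seed = 4L, curve_amp_mm = 1.5))
  mask <- segment_lumen(get_frame(cine))
  cl <- extract_centerline(mask, img$mm_per_px)
  cols <- seq(1, ncol(mask$mask), by = 0.1)
  yc <- approx(seq_along(cine$truth$yc_mm), cine$truth$yc_mm / img$mm_per_px,
               xout = cols)$y
  dev <- vapply(seq_len(nrow(cl$rc)), function(i)
    min(sqrt((cl$rc[i, 1] - yc)^2 + (cl$rc[i, 2] - cols)^2)), numeric(1))
  expect_lt(max(dev), 1.0)
})

test_that("a cyclic skeleton without endpoints is rejected", {
  ring <- matrix(FALSE, 40, 40)
  th <- seq(0, 2 * pi, length.out = 720)
  for (w in seq(10, 14, by = 0.25))
    ring[cbind(round(20 + w * cos(th)), round(20 + w * sin(th)))] <- TRUE
  expect_error(extract_centerline(ring, 0.1), "cyclic")
})

test_that("side-branch pruning keeps the widest continuous path", {
  # branch-free mask is untouched
  band <- matrix(FALSE, 48, 90); band[22:30, 6:84] <- TRUE
  expect_identical(prune_side_branches(band), band)
  # Y-vessel with a thinner oblique branch
  y <- band
  for (k in 0:26) y[(20 - k %/% 2) + 0:2, 45 + k] <- TRUE
  pruned <- prune_side_branches(y)
  expect_false(any(pruned[6:12, 60:71]))            # branch tip removed
  for (col in c(15, 30, 60, 75)) {                  # main widths preserved
    expect_lt(abs(sum(pruned[, col]) - 9), 1.1)
  }
})

test_that("equal-width branches: the longer one is kept, with a warning", {
  m <- matrix(FALSE, 70, 100)
  m[28:32, 5:40] <- TRUE                            # stem
  m[28:32, 41:90] <- TRUE                           # long branch (width 5)
  for (k in 0:24) m[33 + k, 36:40] <- TRUE          # short branch (width 5)
  expect_warning(pruned <- prune_side_branches(m), "indistinguishable")
  expect_true(any(pruned[30, 80:90]))               # long branch retained
  expect_false(any(pruned[52:57, 36:40]))           # short branch removed
})

test_that("diameters of a constant-width band measure w * mm_per_px", {
  band <- matrix(FALSE, 40, 80); band[16:26, 8:72] <- TRUE   # width 11 px
  cl <- extract_centerline(band, 0.1)
  dp <- measure_diameters(band, cl, 0.1)
  mid <- dp$s_mm > 1 & dp$s_mm < max(dp$s_mm) - 1
  expect_lt(max(abs(dp$d_mm[mid] - 11 * 0.1)), 0.1)          # within 1 px
  # doubling the calibration doubles every diameter
  cl2 <- extract_centerline(band, 0.2)
  dp2 <- measure_diameters(band, cl2, 0.2)
  expect_equal(dp2$d_mm, 2 * dp$d_mm, tolerance = 1e-9)
})

test_that("mask-based stenosis measurement locates and sizes the throat", {
  seg <- segment_cine_profile(45)
  img <- seg$cine$imaging
  dp_mask <- measure_diameters(seg$mask, seg$centerline, img$mm_per_px)
  tr <- seg$truth
  s_true <- tr$truth$c - (max(tr$s) - max(dp_mask$s_mm)) / 2
  expect_lt(abs(dp_mask$s_mm[which.min(dp_mask$d_mm)] - s_true), 0.5)
  expect_lt(abs(min(dp_mask$d_mm) - 2 * min(tr$r)), 2 * img$mm_per_px)
})

test_that("rays that cannot exit the mask raise the border error", {
  line <- matrix(FALSE, 30, 60); line[15, 3:58] <- TRUE
  cl <- extract_centerline(line, 0.1, trim_ends = FALSE)
  full <- matrix(TRUE, 30, 60)                      # mask touches every border
  expect_error(measure_diameters(full, cl, 0.1), "border")
})

test_that("subpixel recovery: zero-noise profile error is far below 2 px", {
  seg <- segment_cine_profile(32)
  img <- seg$cine$imaging
  pr <- seg$truth
  off <- (max(pr$s) - max(seg$profile$s_mm)) / 2
  d_true <- approx(pr$s, 2 * pr$r, xout = seg$profile$s_mm + off)$y
  ok <- !is.na(d_true) & seg$profile$s_mm > 1 &
    seg$profile$s_mm < max(seg$profile$s_mm) - 1
  expect_lt(max(abs(seg$profile$d_mm[ok] - d_true[ok])), 2 * img$mm_per_px)
})

test_that("recovery degrades monotonically with imaging noise", {
  mae <- vapply(c(0, 800, 4000), function(ns) {
    seg <- segment_cine_profile(32, noise_sd = ns, seed = 3L)
    pr <- seg$truth
    off <- (max(pr$s) - max(seg$profile$s_mm)) / 2
    d_true <- approx(pr$s, 2 * pr$r, xout = seg$profile$s_mm + off)$y
    ok <- !is.na(d_true) & seg$profile$s_mm > 1 &
      seg$profile$s_mm < max(seg$profile$s_mm) - 1
    mean(abs(seg$profile$d_mm[ok] - d_true[ok]))
  }, numeric(1))
  expect_true(mae[1] <= mae[2] && mae[2] <= mae[3])
})
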