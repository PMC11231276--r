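# Shared fixtures for the test suite.  Everything is generated in code;
# solver cases reuse cached solutions where several tests inspect the same
# run (the runs are deterministic).

straight_tube_grid <- function(n_axial = 60L, n_radial_core = 8L, r0 = 1.5,
                               L = 30) {
  pr <- make_radius_profile(L = L, r0 = r0, beta_target = 0)
  build_grid(as_diameter_profile(pr), n_axial = n_axial,
             n_radial_core = n_radial_core, refine_near_stenosis = FALSE)
}

newtonian_blood <- function(mu = 0.0035) rheology_params(mu0 = mu, mu_inf = mu)

# pressure-driven Newtonian tube flow (tiny outlet resistance ~ fixed 0 Pa)
solve_tube <- function(dp_pa = 100, n_axial = 60L, n_radial_core = 8L,
                       r0 = 1.5, L = 30, cfg = sim_config()) {
  g <- straight_tube_grid(n_axial, n_radial_core, r0, L)
  bc <- assemble_bc(1L, dp_pa / 133.322, list(R = 1e-6, p_ref = 0))
  solve_steady(g, newtonian_blood(), bc, cfg)
}

# cached coarse transient runs keyed by beta/method (used by several tests)
.run_cache <- new.env(parent = emptyenv())
cached_transient <- function(beta, method = 3L, seed = 1L) {
  key <- sprintf("b%s_m%d_s%d", beta, method, seed)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  prof <- as_diameter_profile(make_radius_profile(beta_target = beta))
  g <- build_grid(prof, n_axial = 60L, n_radial_core = 5L)
  cohort <- make_cohort(seed)
  bc <- if (method == 3L) {
    fits <- lapply(cohort, function(p) wk3_fit(p$distal_trace, p$flow)$params)
    assemble_bc(3L, average_waves_fft(lapply(cohort, `[[`, "inlet_wave")),
                average_wk3(fits))
  } else if (method == 2L) {
    assemble_bc(2L, cohort[[1]]$inlet_wave,
                wk3_fit(cohort[[1]]$distal_trace, cohort[[1]]$flow)$params)
  } else stop("cached_transient: method 2 or 3 only")
  hist <- solve_transient(g, rheology_params(), bc, sim_config())
  res <- list(hist = hist, profile = prof,
              stenosis = compute_beta_profile(prof))
  .run_cache[[key]] <- res
  res
}

# sharp diastolic-dominant coronary flow pulse (rich high-frequency content,
# which is what makes the characteristic impedance R1 identifiable)
sharp_flow_wave <- function(n = 1024L, kappa = 20, amp = 1.1, mean_q = 0.6,
                            T = 0.8) {
  t <- seq(0, T, length.out = n + 1L)[seq_len(n)]
  w <- exp(kappa * (cos(2 * pi * (t / T - 0.35)) - 1))
  w <- w - mean(w)
  flow_wave(t, mean_q + amp * w / (max(w) - min(w)), T)
}

# deterministic seeded replicates for sampling-distribution checks
with_seed_test <- function(n, fn) {
  vapply(seq_len(n), function(i) {
    set.seed(1000 + i)
    fn()
  }, logical(1))
}

# segmented profile from a synthetic cine (subpixel path)
segment_cine_profile <- function(beta, noise_sd = 0, seed = 2L,
                                 imaging = imaging_params()) {
  imaging$noise_sd <- noise_sd
  pr <- make_radius_profile(beta_target = beta)
  cine <- normalize_cine(render_cine(pr, imaging, seed = seed))
  frame <- get_frame(cine)
  # pruning may warn about ambiguous blobs on very noisy masks
  mask <- suppressWarnings(prune_side_branches(segment_lumen(frame)))
  cl <- extract_centerline(mask, imaging$mm_per_px)
  list(profile = measure_diameters(mask, cl, imaging$mm_per_px, frame = frame),
       truth = pr, cine = cine, mask = mask, centerline = cl, frame = frame)
}
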