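#' Simulation configuration
#'
#' Numerical settings for the finite-volume solver.  Defaults follow the
#' study conditions: 0.005 s time step, second-order backward time scheme
#' (first step bootstrapped first-order), three cardiac cycles with the last
#' one extracted, and a normalised RMS residual tolerance of 1e-5.
#'
#' @param dt time step (s)
#' @param n_cycles cardiac cycles to run (results use the final one)
#' @param tol normalised residual tolerance
#' @param relax_u,relax_p under-relaxation factors (momentum / pressure)
#' @param relax_wk relaxation of the Windkessel outlet sub-iteration
#' @param max_inner inner (per-time-step) iteration cap
#' @param max_outer outer iteration cap for steady solves
#' @param blend deferred central-correction blending of the convection scheme
#'   (0 = pure upwind, 1 = central)
#' @param gs_sweeps Gauss-Seidel sweeps per momentum solve
#' @param cg_tol,cg_max relative tolerance and iteration cap of the pressure
#'   Poisson CG solver
#' @return object of class `sim_config`
#' @export
sim_config <- function(dt = 0.005, n_cycles = 3L, tol = 1e-5,
                       relax_u = 0.7, relax_p = 0.3, relax_wk = 0.5,
                       max_inner = 250L, max_outer = 6000L, blend = 0.5,
                       gs_sweeps = 5L, cg_tol = 0.02, cg_max = 400L) {
  stopifnot(dt > 0, tol > 0, n_cycles >= 1L)
  structure(list(dt = dt, n_cycles = as.integer(n_cycles), tol = tol,
                 relax_u = relax_u, relax_p = relax_p, relax_wk = relax_wk,
                 max_inner = as.integer(max_inner),
                 max_outer = as.integer(max_outer), blend = blend,
                 gs_sweeps = as.integer(gs_sweeps), cg_tol = cg_tol,
                 cg_max = as.integer(cg_max)),
            class = "sim_config")
}

#' Assemble and validate a boundary-condition specification
#'
#' The four methodologies:
#' \describe{
#' \item{1}{constant steady inlet pressure, patient-specific resistance
#'   outlet (`outlet_data = list(R = ..., p_ref = 0)`, mmHg s/ml)}
#' \item{2}{patient-specific transient inlet [pressure_wave()], patient-specific
#'   [wk3_params()] outlet}
#' \item{3}{average transient inlet wave, average [wk3_params()] outlet}
#' \item{4}{transient pressure waves at both inlet and outlet}
#' }
#' All methods assume rigid, no-slip walls.
#'
#' @param method integer 1-4
#' @param inlet_data numeric scalar (mmHg) for method 1, otherwise a
#'   [pressure_wave()]
#' @param outlet_data per method: resistance list, [wk3_params()], or a
#'   [pressure_wave()]
#' @return object of class `bc_spec`
#' @export
assemble_bc <- function(method, inlet_data, outlet_data) {
  if (!method %in% 1:4)
    stop("assemble_bc: method must be 1, 2, 3 or 4")
  method <- as.integer(method)
  if (method == 1L) {
    if (!is.numeric(inlet_data) || length(inlet_data) != 1L)
      stop("assemble_bc: method 1 needs a constant inlet pressure (mmHg)")
    if (!is.list(outlet_data) || is.null(outlet_data$R) || outlet_data$R <= 0)
      stop("assemble_bc: method 1 needs an outlet resistance list(R=, p_ref=)")
    outlet_data$p_ref <- outlet_data$p_ref %||% 0
  } else {
    if (!inherits(inlet_data, "pressure_wave"))
      stop("assemble_bc: methods 2-4 need a pressure_wave at the inlet")
    if (method %in% c(2L, 3L)) {
      if (!inherits(outlet_data, "wk3_params"))
        stop("assemble_bc: methods 2 and 3 need wk3_params at the outlet")
    } else {
      if (!inherits(outlet_data, "pressure_wave"))
        stop("assemble_bc: method 4 needs a pressure_wave at the outlet")
      if (abs(outlet_data$period - inlet_data$period) > 1e-9 * inlet_data$period)
        stop("assemble_bc: inlet and outlet waves must share one period")
    }
  }
  structure(list(method = method, inlet = inlet_data, outlet = outlet_data,
                 wall = "rigid-no-slip",
                 tag = c("steady-resistance", "patient-specific",
                         "average BCs", "transient-transient")[method]),
            class = "bc_spec")
}

#' @export
print.bc_spec <- function(x, ...) {
  cat(sprintf("bc_spec: method %d (%s), rigid no-slip wall\n", x$method, x$tag))
  invisible(x)
}

solver_opts <- function(rheology, cfg) {
  list(rho = rheology$rho, mu0 = rheology$mu0, mu_inf = rheology$mu_inf,
       lambda_cy = rheology$lambda_cy, a = rheology$a, m = rheology$m,
       relax_u = cfg$relax_u, relax_p = cfg$relax_p, relax_wk = cfg$relax_wk,
       blend = cfg$blend, tol = cfg$tol, cg_tol = cfg$cg_tol,
       gs_sweeps = cfg$gs_sweeps, cg_max = cfg$cg_max, dt = cfg$dt)
}

grid_nodes_m <- function(grid) {
  list(Z = grid$Z * MM_M, R = grid$R * MM_M)
}

#' Steady flow solution (boundary-condition method 1)
#'
#' Converges the steady incompressible Navier-Stokes equations with a
#' constant inlet pressure and a linear-resistance outlet
#' (`P_out = p_ref + R * Q_out`, the Hagen-Poiseuille outlet law).
#'
#' @param grid a [build_grid()] grid
#' @param rheology [rheology_params()]
#' @param bc an [assemble_bc()] spec with `method = 1`
#' @param cfg [sim_config()]
#' @return object of class `flow_field`: cell-centre `uz`, `ur` (m/s), `p`
#'   (Pa), centre coordinates `zc`, `rc` (m), volumes, flows `q_in`, `q_out`
#'   (m3/s), convergence info
#' @export
solve_steady <- function(grid, rheology, bc, cfg = sim_config()) {
  stopifnot(inherits(grid, "vessel_grid"), inherits(bc, "bc_spec"))
  if (bc$method != 1L)
    stop("solve_steady: requires a method-1 (steady) bc_spec")
  nd <- grid_nodes_m(grid)
  opts <- solver_opts(rheology, cfg)
  opts$p_in <- mmHg_to_Pa(bc$inlet)
  opts$outlet_type <- 1L
  opts$res_R <- res_to_si(bc$outlet$R)
  opts$res_pref <- mmHg_to_Pa(bc$outlet$p_ref)
  opts$max_outer <- cfg$max_outer
  out <- cpp_solve_steady(nd$Z, nd$R, opts)
  if (!out$converged)
    stop(sprintf("solve_steady: no convergence in %d iterations (final residual %.3g); residual history attached",
                 out$iterations, max(out$res_final)))
  structure(c(out, list(grid = grid, rheology = rheology, bc = bc, cfg = cfg)),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("flow_field: %d x %d cells, Q = %.3f ml/s, dP = %.2f mmHg (%d iterations)\n",
              nrow(x$p), ncol(x$p), x$q_in / ML_M3,
              Pa_to_mmHg(section_pressure(x, 1) - section_pressure(x, nrow(x$p))),
              x$iterations))
  invisible(x)
}

# Area-weighted cross-section average of cell pressure at axial station i.
section_pressure <- function(field, i) {
  w <- field$vol[i, ]
  sum(field$p[i, ] * w) / sum(w)
}

#' Transient flow solution (boundary-condition methods 2, 3, 4)
#'
#' Runs `cfg$n_cycles` cardiac cycles of the pulsatile problem with BDF2 time
#' stepping and returns the final cycle.  Methods 2 and 3 couple a
#' three-element Windkessel at the outlet by relaxed sub-iteration inside
#' every time step (converged when the outlet pressure moves by less than
#' 1e-3 mmHg); method 4 imposes the recorded outlet pressure wave.
#'
#' @inheritParams solve_steady
#' @param bc an [assemble_bc()] spec with method 2, 3 or 4
#' @return object of class `field_history`: arrays `uz`, `ur` (m/s), `p` (Pa)
#'   of dimension (n_axial, n_radial, n_steps) over the final cycle, cell
#'   coordinates, full-run traces `q_in`, `q_out` (m3/s), `p_out` (Pa),
#'   residuals and periodicity metric
#' @export
solve_transient <- function(grid, rheology, bc, cfg = sim_config()) {
  stopifnot(inherits(grid, "vessel_grid"), inherits(bc, "bc_spec"))
  if (!bc$method %in% 2:4)
    stop("solve_transient: requires a method-2, 3 or 4 bc_spec")
  T <- bc$inlet$period
  steps_per_cycle <- round(T / cfg$dt)
  if (abs(steps_per_cycle * cfg$dt - T) > 1e-9 * T)
    stop("solve_transient: dt must divide the period T")
  if (steps_per_cycle < 8L) stop("solve_transient: dt too coarse for the period")
  nsteps <- steps_per_cycle * cfg$n_cycles
  tgrid <- (seq_len(nsteps)) * cfg$dt
  nd <- grid_nodes_m(grid)
  opts <- solver_opts(rheology, cfg)
  opts$p_in_series <- mmHg_to_Pa(wave_interp(bc$inlet$t, bc$inlet$p, T, tgrid))
  opts$store_from <- nsteps - steps_per_cycle + 1L
  opts$max_inner <- cfg$max_inner
  if (bc$method == 4L) {
    opts$outlet_type <- 0L
    opts$p_out_series <- mmHg_to_Pa(wave_interp(bc$outlet$t, bc$outlet$p, T, tgrid))
  } else {
    opts$outlet_type <- 2L
    opts$wk_R1 <- res_to_si(bc$outlet$R1)
    opts$wk_R2 <- res_to_si(bc$outlet$R2)
    opts$wk_C <- cap_to_si(bc$outlet$C)
    opts$wk_p0 <- mean(opts$p_in_series) * 0.98
  }
  out <- cpp_solve_transient(nd$Z, nd$R, opts)
  nz <- out$nz; nr <- out$nr; ns <- out$nstore
  # C++ flattens cells as c = i*nr + j (j fastest) -> dim (nr, nz, ns);
  # transpose to (nz, nr, ns)
  arr <- function(v) aperm(array(v, dim = c(nr, nz, ns)), c(2, 1, 3))
  hist <- list(
    uz = arr(out$uz), ur = arr(out$ur), p = arr(out$p),
    zc = out$zc, rc = out$rc, vol = out$vol,
    t = out$t, q_in = out$q_in, q_out = out$q_out,
    p_out = out$p_out, p_in = out$p_in,
    inner_iterations = out$inner_iterations,
    step_converged = out$step_converged,
    wk_subconverged = out$wk_subconverged,
    res_final = out$res_final,
    stored_steps = seq.int(opts$store_from, nsteps),
    steps_per_cycle = steps_per_cycle, period = T, dt = cfg$dt,
    grid = grid, rheology = rheology, bc = bc, cfg = cfg)
  hist$converged <- all(out$step_converged)
  # periodicity of the final two cycles (inlet flow trace)
  if (cfg$n_cycles >= 2L) {
    q1 <- out$q_in[(nsteps - 2L * steps_per_cycle + 1L):(nsteps - steps_per_cycle)]
    q2 <- out$q_in[(nsteps - steps_per_cycle + 1L):nsteps]
    rng <- max(abs(q2), 1e-30)
    hist$cycle_change <- sqrt(mean((q2 - q1)^2)) / rng
    if (hist$cycle_change > 0.02)
      warning(sprintf("solve_transient: final cycle differs from the previous one by %.2g%% RMS; periodic state questionable",
                      100 * hist$cycle_change))
  }
  structure(hist, class = "field_history")
}

#' @export
print.field_history <- function(x, ...) {
  cat(sprintf("field_history: %d x %d cells, %d stored steps (T = %g s, dt = %g s)\n",
              dim(x$p)[1], dim(x$p)[2], dim(x$p)[3], x$period, x$dt))
  if (!is.null(x$cycle_change))
    cat(sprintf("  cycle-to-cycle change %.3g%%, mean Q_in %.3f ml/s\n",
                100 * x$cycle_change, mean(tail(x$q_in, x$steps_per_cycle)) / ML_M3))
  invisible(x)
}

#' Advance the Windkessel outlet pressure by one relaxed sub-iteration
#'
#' The 0D-3D coupling rule used inside each solver time step: the WK3
#' equation is discretised implicitly in the outlet pressure given the
#' instantaneous outlet flow, and the outlet pressure is moved a fraction
#' `relax` toward that target.  Sub-iteration is converged when the update
#' falls below 1e-3 mmHg.
#'
#' @param state list with `p_prev`, `q_prev` (previous time-step outlet
#'   pressure mmHg and flow ml/s), `q_now` (current iterate flow, ml/s) and
#'   `p_guess` (current iterate pressure, mmHg)
#' @param wk [wk3_params()]
#' @param dt time step (s)
#' @param relax relaxation factor in (0, 1]
#' @return list with `p` (next iterate, mmHg), `target` (implicit solution),
#'   `converged` (update below 1e-3 mmHg)
#' @export
couple_wk3_outlet <- function(state, wk, dt, relax = 0.5) {
  stopifnot(inherits(wk, "wk3_params"), dt > 0)
  tc <- wk$R2 * wk$C
  target <- (tc / dt * state$p_prev + (wk$R1 + wk$R2) * state$q_now +
               wk$R1 * tc * (state$q_now - state$q_prev) / dt) /
    (1 + tc / dt)
  p_new <- state$p_guess + relax * (target - state$p_guess)
  list(p = p_new, target = target,
       converged = abs(p_new - state$p_guess) < 1e-3)
}
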