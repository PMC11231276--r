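#' Three-element Windkessel parameters
#'
#' Lumped (0D) model of the distal vasculature: characteristic impedance `R1`
#' in series with the parallel combination of hydrodynamic resistance `R2`
#' and compliance `C`.  Pressure and flow obey
#' \deqn{P = (R_1+R_2)Q - R_2 C \frac{dP}{dt} + R_1 R_2 C \frac{dQ}{dt}.}
#'
#' @param R1 characteristic impedance (mmHg s/ml)
#' @param R2 hydrodynamic resistance (mmHg s/ml)
#' @param C compliance (ml/mmHg)
#' @return object of class `wk3_params`
#' @export
wk3_params <- function(R1, R2, C) {
  if (!all(is.finite(c(R1, R2, C))) || any(c(R1, R2, C) <= 0))
    stop("wk3_params: R1, R2 and C must be strictly positive")
  structure(list(R1 = R1, R2 = R2, C = C), class = "wk3_params")
}

#' @export
print.wk3_params <- function(x, ...) {
  cat(sprintf("WK3: R1 = %g, R2 = %g mmHg.s/ml, C = %g ml/mmHg\n",
              x$R1, x$R2, x$C))
  invisible(x)
}

#' Hagen-Poiseuille pressure drop
#'
#' Linear resistance law \eqn{\Delta P = R\,Q} used by the steady
#' boundary-condition methodology.
#'
#' @param R resistance (mmHg s/ml), must be positive
#' @param Q flow (ml/s), vectorised
#' @return pressure drop (mmHg)
#' @export
poiseuille_dp <- function(R, Q) {
  if (!is.numeric(R) || any(R <= 0)) stop("poiseuille_dp: R must be > 0")
  R * Q
}

#' Integrate the three-element Windkessel ODE
#'
#' Time-domain integration of the WK3 pressure response to a periodic flow
#' wave.  Internally the stiff `dQ/dt` term is removed by integrating the
#' capacitor pressure `Pc` (`dPc/dt = (Q - Pc/R2)/C`, `P = Pc + R1 Q`), which
#' is algebraically identical to the WK3 equation; the ODE is advanced with
#' classical RK4 (the flow wave is interpolated periodically at stage times).
#' Integration proceeds for up to `n_periods` cycles, stopping early once two
#' consecutive periods agree to machine-level tolerance, and the final period
#' is returned.
#'
#' @param Q a [flow_wave()] (ml/s); must be periodic
#' @param params [wk3_params()]
#' @param dt integration step (s), must satisfy `dt <= T/50`; default `T/500`
#' @param p_init initial pressure (mmHg); default the steady value
#'   `(R1+R2)*mean(Q)`
#' @param n_periods maximum number of cycles to integrate (>= 1)
#' @return a [pressure_wave()] holding the final integrated period
#' @export
wk3_solve <- function(Q, params, dt = NULL, p_init = NULL, n_periods = 20L) {
  stopifnot(inherits(Q, "flow_wave"), inherits(params, "wk3_params"))
  T <- Q$period
  if (is.null(dt)) dt <- T / 500
  n <- round(T / dt)
  if (n < 50) stop("wk3_solve: need dt <= T/50")
  dt <- T / n
  R1 <- params$R1; R2 <- params$R2; C <- params$C
  qf <- function(tt) wave_interp(Q$t, Q$q, T, tt)
  if (is.null(p_init)) p_init <- (R1 + R2) * mean(Q$q)
  pc <- p_init - R1 * qf(0)
  tgrid <- (seq_len(n) - 1L) * dt
  qgrid <- qf(tgrid)
  qhalf <- qf(tgrid + dt / 2)
  qnext <- c(qgrid[-1L], qgrid[1L])
  deriv <- function(pc, q) (q - pc / R2) / C
  prev <- NULL
  for (cyc in seq_len(max(1L, as.integer(n_periods)))) {
    ptrace <- numeric(n)
    for (i in seq_len(n)) {
      ptrace[i] <- pc + R1 * qgrid[i]
      k1 <- deriv(pc, qgrid[i])
      k2 <- deriv(pc + dt / 2 * k1, qhalf[i])
      k3 <- deriv(pc + dt / 2 * k2, qhalf[i])
      k4 <- deriv(pc + dt * k3, qnext[i])
      pc <- pc + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (!is.null(prev)) {
      scale <- mean(abs(ptrace)) + 1e-12
      if (sqrt(mean((ptrace - prev)^2)) < 1e-10 * scale) break
    }
    prev <- ptrace
  }
  pressure_wave(tgrid, ptrace, T)
}

# Exact periodic WK3 response via the impedance transfer function
# Z(w) = R1 + R2/(1 + i w R2 C); used as the model inside wk3_fit.
wk3_periodic_response <- function(q, T, R1, R2, C) {
  n <- length(q)
  qh <- fft(q)
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  w <- 2 * pi * k / T
  Z <- R1 + R2 / (1 + 1i * w * R2 * C)
  Re(fft(qh * Z, inverse = TRUE)) / n
}

#' Fit three-element Windkessel parameters to a measured distal pressure
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt on log-parameters)
#' minimising the sum of squared differences between the periodic WK3
#' response to `Q` and the measured pressure wave.  Deterministic given the
#' initial guess.  The default initialiser takes `R1+R2 = mean(P)/mean(Q)`
#' split 20/80 and a compliance giving an `R2*C` decay time of half a period.
#'
#' If both waves are (numerically) constant, `C` is structurally
#' unidentifiable: only `R1+R2` is returned (split as in `init`), with
#' `degenerate = TRUE` and a warning.
#'
#' @param p_meas measured distal [pressure_wave()] (mmHg)
#' @param Q the driving [flow_wave()] (ml/s); resampled to a common grid with
#'   `p_meas` if needed
#' @param init optional [wk3_params()] initial guess
#' @param bounds optional list with `lower` and `upper` numeric vectors
#'   `(R1, R2, C)`
#' @param max_iter iteration cap for the optimiser
#' @return a list with elements `params` ([wk3_params()]), `sse`,
#'   `iterations`, `converged`, `degenerate`
#' @export
wk3_fit <- function(p_meas, Q, init = NULL, bounds = NULL, max_iter = 200L) {
  stopifnot(inherits(p_meas, "pressure_wave"), inherits(Q, "flow_wave"))
  if (abs(p_meas$period - Q$period) > 1e-9 * Q$period)
    stop("wk3_fit: pressure and flow waves must share the same period")
  n <- max(length(p_meas$t), length(Q$t))
  if (length(p_meas$t) != n) p_meas <- wave_resample(p_meas, n)
  if (length(Q$t) != n) Q <- wave_resample(Q, n)
  T <- Q$period; p <- p_meas$p; q <- Q$q

  mq <- mean(q); mp <- mean(p)
  if (mq <= 0) stop("wk3_fit: mean flow must be positive")
  if (is.null(init)) {
    rtot <- mp / mq
    init <- wk3_params(0.2 * rtot, 0.8 * rtot, 0.5 * T / (0.8 * rtot))
  }
  if (sd(q) < 1e-10 * abs(mq) && sd(p) < 1e-10 * abs(mp)) {
    warning("wk3_fit: constant flow and pressure; only R1+R2 identifiable, C unidentifiable")
    rtot <- mp / mq
    split <- init$R1 / (init$R1 + init$R2)
    return(list(params = wk3_params(split * rtot, (1 - split) * rtot, init$C),
                sse = sum((p - mp)^2), iterations = 0L,
                converged = TRUE, degenerate = TRUE))
  }
  lower <- log(bounds$lower %||% c(1e-6, 1e-4, 1e-8))
  upper <- log(bounds$upper %||% c(1e3, 1e5, 1e2))
  resid <- function(theta) {
    th <- exp(theta)
    wk3_periodic_response(q, T, th[1], th[2], th[3]) - p
  }
  fit <- minpack.lm::nls.lm(
    par = log(c(init$R1, init$R2, init$C)),
    lower = lower, upper = upper, fn = resid,
    control = minpack.lm::nls.lm.control(maxiter = as.integer(max_iter),
                                         ftol = 1e-14, ptol = 1e-14))
  ok <- fit$info %in% 1:4
  if (!ok)
    warning(sprintf("wk3_fit: optimiser stopped without convergence (info %d); returning best-so-far (SSE %.4g)",
                    fit$info, fit$deviance))
  th <- exp(fit$par)
  list(params = wk3_params(th[1], th[2], th[3]),
       sse = fit$deviance, iterations = fit$niter,
       converged = ok, degenerate = FALSE)
}

#' Average Windkessel parameter sets component-wise
#'
#' Arithmetic mean of each parameter over a cohort, the construction behind
#' the "average boundary condition" methodology.
#'
#' @param params_list non-empty list of [wk3_params()]
#' @return a [wk3_params()] with component-wise means
#' @export
#' @examples
#' avg <- average_wk3(lapply(seq_len(5), function(i)
#'   with(cohort_reference()[i, ], wk3_params(R1, R2, C))))
#' avg$R1   # 0.2622364
average_wk3 <- function(params_list) {
  if (length(params_list) == 0L) stop("average_wk3: empty parameter list")
  stopifnot(all(vapply(params_list, inherits, logical(1), "wk3_params")))
  wk3_params(mean(vapply(params_list, `[[`, numeric(1), "R1")),
             mean(vapply(params_list, `[[`, numeric(1), "R2")),
             mean(vapply(params_list, `[[`, numeric(1), "C")))
}

#' Ensemble-average pressure waves through the frequency domain
#'
#' Averages a cohort of periodic pressure waves by (i) taking the FFT of each
#' signal, (ii) averaging the spectra element-wise, and (iii) inverse
#' transforming.  Waves of unequal length are first resampled (periodic
#' linear interpolation) onto a common grid with as many samples as the
#' finest input; the output period is the mean of the input periods.
#' For equal-length inputs this is algebraically identical to the pointwise
#' time-domain mean.
#'
#' Optionally (`scale_to`) the averaged wave can be rescaled post hoc so its
#' mean matches a reference patient's mean pressure; this mirrors the idea of
#' anchoring the averaged inlet wave to one patient's pressure level, and is
#' off by default because the choice of anchor is an open one.
#'
#' @param waves non-empty list of [pressure_wave()]
#' @param scale_to optional reference: a [pressure_wave()] or a numeric mean
#'   pressure (mmHg) the averaged wave's mean is rescaled to
#' @return the averaged [pressure_wave()]
#' @export
average_waves_fft <- function(waves, scale_to = NULL) {
  if (length(waves) == 0L) stop("average_waves_fft: empty wave list")
  stopifnot(all(vapply(waves, inherits, logical(1), "pressure_wave")))
  n <- max(vapply(waves, function(w) length(w$t), integer(1)))
  waves <- lapply(waves, function(w)
    if (length(w$t) == n) w else wave_resample(w, n))
  spec <- Reduce(`+`, lapply(waves, function(w) fft(w$p))) / length(waves)
  pbar <- Re(fft(spec, inverse = TRUE)) / n
  Tbar <- mean(vapply(waves, `[[`, numeric(1), "period"))
  if (!is.null(scale_to)) {
    ref <- if (inherits(scale_to, "pressure_wave")) mean(scale_to$p) else scale_to
    pbar <- pbar * ref / mean(pbar)
  }
  t <- seq(0, Tbar, length.out = n + 1L)[seq_len(n)]
  pressure_wave(t, pbar, Tbar)
}

#' Percentage error between patient-specific and average Windkessel parameters
#'
#' Reports `100*|ps - avg|/ps` per component, truncated toward zero to an
#' integer — the convention used by the published comparison tables (26.9%
#' prints as 26, 8.96% as 8).
#'
#' @param ps patient-specific [wk3_params()]
#' @param avg average [wk3_params()]
#' @return named integer vector `(R1, R2, C)` of percent errors
#' @export
wk3_error_report <- function(ps, avg) {
  stopifnot(inherits(ps, "wk3_params"), inherits(avg, "wk3_params"))
  err <- function(a, b) as.integer(trunc_guard(100 * abs(a - b) / a, 0L))
  c(R1 = err(ps$R1, avg$R1), R2 = err(ps$R2, avg$R2), C = err(ps$C, avg$C))
}

#' Bundled reference cohort
#'
#' Five patient-specific parameter sets (three-element Windkessel parameters,
#' degree of stenosis, and invasive vs computed FFR under patient-specific
#' and average boundary conditions) bundled as reference inputs for the
#' averaging and error-reporting arithmetic and as physiologically grounded
#' defaults for the synthetic cohort generator.
#'
#' @return data.frame with columns `patient`, `ffr_invasive`,
#'   `ffr_virtual_ps` (patient-specific BCs), `ffr_virtual_avg` (average BCs),
#'   `beta` (%), `R1`, `R2` (mmHg s/ml), `C` (ml/mmHg)
#' @export
cohort_reference <- function() {
  data.frame(
    patient = 1:5,
    ffr_invasive    = c(0.89, 0.85, 0.84, 0.89, 0.86),
    ffr_virtual_ps  = c(0.885, 0.87, 0.869, 0.90, 0.862),
    ffr_virtual_avg = c(0.892, 0.87, 0.85, 0.93, 0.87),
    beta = c(32, 20, 18, 45, 36),
    R1 = c(0.39713, 0.2138, 0.335892, 0.10599, 0.25837),
    R2 = c(163.28846, 76.02368, 151.69549, 68.12693, 128.63917),
    C  = c(0.00357, 0.00355, 0.00255, 0.00354, 0.00297))
}
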