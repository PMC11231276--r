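#' Periodic pressure wave
#'
#' Container for a uniformly sampled periodic pressure signal.  Samples cover
#' one period `[0, T)`; the endpoint is excluded (wraps to `t = 0`).
#'
#' @param t time samples (s), uniform, starting at 0
#' @param p pressure samples (mmHg)
#' @param period cycle duration T (s)
#' @return object of class `pressure_wave`
#' @export
pressure_wave <- function(t, p, period) {
  check_wave_grid(t, p, period, "pressure_wave")
  structure(list(t = t, p = p, period = period), class = "pressure_wave")
}

#' Periodic flow wave
#'
#' @param t time samples (s), uniform, starting at 0
#' @param q volumetric flow samples (ml/s)
#' @param period cycle duration T (s)
#' @return object of class `flow_wave`
#' @export
flow_wave <- function(t, q, period) {
  check_wave_grid(t, q, period, "flow_wave")
  structure(list(t = t, q = q, period = period), class = "flow_wave")
}

check_wave_grid <- function(t, y, period, what) {
  if (length(t) != length(y) || length(t) < 2L)
    stop(what, ": time and value vectors must have equal length >= 2")
  if (!all(is.finite(t)) || !all(is.finite(y)))
    stop(what, ": samples must be finite")
  if (!is.numeric(period) || period <= 0) stop(what, ": period must be > 0")
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-9 * max(dt[1], 1e-12)))
    stop(what, ": samples must be uniform in time")
  invisible(TRUE)
}

#' @export
print.pressure_wave <- function(x, ...) {
  cat(sprintf("pressure_wave: %d samples over T = %g s, mean %.2f mmHg, range [%.2f, %.2f]\n",
              length(x$t), x$period, mean(x$p), min(x$p), max(x$p)))
  invisible(x)
}

#' @export
print.flow_wave <- function(x, ...) {
  cat(sprintf("flow_wave: %d samples over T = %g s, mean %.3f ml/s\n",
              length(x$t), x$period, mean(x$q)))
  invisible(x)
}

# Truncated-Fourier periodic bump (von Mises shape), unit mean over the grid.
# Used to synthesise aortic-like pressure and coronary-like flow shapes.
fourier_bump <- function(x, centre, kappa, n_harmonics) {
  w <- rep(1, length(x))
  for (k in seq_len(n_harmonics)) {
    ak <- besselI(kappa, k) / besselI(kappa, 0)
    w <- w + 2 * ak * cos(2 * pi * k * (x - centre))
  }
  w
}

#' Synthesise an aortic-like periodic pressure wave
#'
#' Builds a smooth periodic signal from a truncated Fourier series (a systolic
#' bump plus a smaller dicrotic bump).  The sample mean equals `mean` exactly
#' (the harmonics are alias-free on the grid) and the on-grid peak-to-peak
#' equals `pulse_amplitude` exactly.
#'
#' Defaults emulate a hyperaemic proximal coronary/aortic pressure: mean
#' 75 mmHg (the study's printed inlet pressure level), 40 mmHg pulse,
#' T = 0.8 s.
#'
#' @param mean temporal mean pressure (mmHg)
#' @param pulse_amplitude peak-to-peak amplitude (mmHg); 0 gives a constant wave
#' @param T period (s)
#' @param n_harmonics number of Fourier harmonics kept (>= 1)
#' @param n_samples samples per period (>= 8 and > 2*n_harmonics)
#' @return a [pressure_wave()]
#' @export
make_pressure_wave <- function(mean = 75, pulse_amplitude = 40, T = 0.8,
                               n_harmonics = 8L, n_samples = 256L) {
  stopifnot(T > 0, n_samples >= 8L, n_harmonics >= 1L)
  if (n_samples <= 2L * n_harmonics)
    stop("make_pressure_wave: need n_samples > 2*n_harmonics (alias-free grid)")
  t <- seq(0, T, length.out = n_samples + 1L)[seq_len(n_samples)]
  x <- t / T
  if (pulse_amplitude == 0) {
    p <- rep(mean, n_samples)
  } else {
    w <- fourier_bump(x, 0.16, 9, n_harmonics) +
      0.35 * fourier_bump(x, 0.45, 30, n_harmonics)
    w <- w - base::mean(w)                       # exact zero sample mean
    p <- mean + pulse_amplitude * w / (max(w) - min(w))
  }
  if (any(p < 0))
    stop(sprintf(paste0("make_pressure_wave: negative pressures produced ",
                        "(min %.2f mmHg); increase mean or reduce amplitude"),
                 min(p)))
  pressure_wave(t, p, T)
}

#' Synthesise a coronary-like periodic flow wave
#'
#' Diastolic-dominant periodic flow shape built like [make_pressure_wave()].
#' Default mean 0.65 ml/s matches the flow implied by the bundled cohort's
#' mean pressure and total Windkessel resistance.
#'
#' @param mean temporal mean flow (ml/s)
#' @param pulse_amplitude peak-to-peak amplitude (ml/s)
#' @param T period (s)
#' @param n_harmonics,n_samples as in [make_pressure_wave()]
#' @return a [flow_wave()]
#' @export
make_flow_wave <- function(mean = 0.65, pulse_amplitude = 0.6, T = 0.8,
                           n_harmonics = 8L, n_samples = 256L) {
  stopifnot(T > 0, n_samples >= 8L, n_harmonics >= 1L)
  if (n_samples <= 2L * n_harmonics)
    stop("make_flow_wave: need n_samples > 2*n_harmonics")
  t <- seq(0, T, length.out = n_samples + 1L)[seq_len(n_samples)]
  x <- t / T
  if (pulse_amplitude == 0) {
    q <- rep(mean, n_samples)
  } else {
    w <- fourier_bump(x, 0.62, 5, n_harmonics)
    w <- w - base::mean(w)
    q <- mean + pulse_amplitude * w / (max(w) - min(w))
  }
  flow_wave(t, q, T)
}

# Periodic linear interpolation of a wave at arbitrary times.
wave_interp <- function(t, y, period, tq) {
  n <- length(t)
  dt <- period / n
  tq <- tq %% period
  i0 <- floor(tq / dt)
  frac <- tq / dt - i0
  i0 <- (as.integer(i0) %% n) + 1L
  i1 <- (i0 %% n) + 1L
  y[i0] * (1 - frac) + y[i1] * frac
}

# Resample a wave onto n uniform samples per period (periodic linear interp).
wave_resample <- function(w, n) {
  tq <- seq(0, w$period, length.out = n + 1L)[seq_len(n)]
  yname <- if (inherits(w, "flow_wave")) "q" else "p"
  y <- wave_interp(w$t, w[[yname]], w$period, tq)
  if (inherits(w, "flow_wave")) flow_wave(tq, y, w$period)
  else pressure_wave(tq, y, w$period)
}

#' Write / read a wave as two-column CSV
#'
#' Files use unit-suffixed headers `time_s` and `pressure_mmHg` (or
#' `flow_ml_s`); the period is recovered from the uniform grid on read.
#'
#' @param wave a [pressure_wave()] or [flow_wave()]
#' @param file path to CSV
#' @return `write_wave_csv` returns `file` invisibly; `read_wave_csv` returns
#'   the wave object.
#' @export
write_wave_csv <- function(wave, file) {
  if (inherits(wave, "flow_wave")) {
    df <- data.frame(time_s = wave$t, flow_ml_s = wave$q)
  } else {
    df <- data.frame(time_s = wave$t, pressure_mmHg = wave$p)
  }
  write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_wave_csv
#' @export
read_wave_csv <- function(file) {
  df <- read.csv(file)
  t <- df$time_s
  period <- t[length(t)] + (t[2] - t[1])   # samples cover [0, T)
  if ("flow_ml_s" %in% names(df)) flow_wave(t, df$flow_ml_s, period)
  else pressure_wave(t, df$pressure_mmHg, period)
}
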