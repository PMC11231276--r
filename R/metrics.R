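#' Wall shear stress history along the vessel wall
#'
#' Evaluates the viscous traction at the wall from the wall-adjacent cell:
#' the wall shear rate is the tangential cell velocity divided by the
#' wall-normal distance (no-slip), the viscosity is the Carreau-Yasuda value
#' at that shear rate, and the sign follows the local axial flow direction
#' (positive with the mean flow).  In axisymmetric flow only the meridional
#' component exists; there is no circumferential WSS.
#'
#' @param history a [solve_transient()] `field_history` (or a steady
#'   `flow_field`)
#' @param rheology optional [rheology_params()] override (defaults to the one
#'   stored in `history`)
#' @return object of class `wall_wss`: `s_mm` wall stations, `wss` matrix
#'   (stations x time, Pa, signed), `t`, `period`
#' @export
wall_shear <- function(history, rheology = NULL) {
  rheology <- rheology %||% history$rheology
  grid <- history$grid
  nz <- grid$n_axial; nr <- grid$n_radial
  # wall face geometry (mm -> m)
  zl <- grid$Z[, nr + 1L] * MM_M; rl <- grid$R[, nr + 1L] * MM_M
  fx <- (zl[-1L] + zl[-(nz + 1L)]) / 2; fy <- (rl[-1L] + rl[-(nz + 1L)]) / 2
  tx <- diff(zl); ty <- diff(rl)
  tl <- sqrt(tx^2 + ty^2); tx <- tx / tl; ty <- ty / tl     # wall tangent (+z sense)
  steady <- inherits(history, "flow_field")
  nt <- if (steady) 1L else dim(history$p)[3]
  zc <- history$zc[, nr]; rc <- history$rc[, nr]
  dn <- abs((zc - fx) * (-ty) + (rc - fy) * tx)             # wall-normal distance
  wss <- matrix(0, nz, nt)
  for (k in seq_len(nt)) {
    uzk <- if (steady) history$uz[, nr] else history$uz[, nr, k]
    urk <- if (steady) history$ur[, nr] else history$ur[, nr, k]
    ut <- uzk * tx + urk * ty
    gam <- abs(ut) / dn
    wss[, k] <- sign(ut) * viscosity(gam, rheology) * gam
  }
  s_wall <- cumsum(c(0, sqrt(diff(zl)^2 + diff(rl)^2))) / MM_M
  s_mid <- (s_wall[-1L] + s_wall[-(nz + 1L)]) / 2
  structure(list(s_mm = s_mid, wss = wss,
                 t = if (steady) 0 else history$t[history$stored_steps],
                 period = if (steady) NA_real_ else history$period),
            class = "wall_wss")
}

check_cycle <- function(wss, T) {
  if (is.matrix(wss) && ncol(wss) < 2L)
    stop("metrics: need a full cycle of WSS samples")
  invisible(TRUE)
}

#' Time-averaged wall shear stress
#'
#' \deqn{TAWSS = \frac1T \int_0^T |WSS(t)|\,dt,} evaluated by trapezoidal
#' quadrature over one period (the signal is treated as periodic, so the
#' wrap-around interval is included).
#'
#' @param wss matrix (stations x time) of signed WSS samples covering one
#'   cycle (or a `wall_wss` object)
#' @param T cycle duration (s); taken from the object if omitted
#' @return numeric vector of TAWSS per station (Pa)
#' @export
tawss <- function(wss, T = NULL) {
  if (inherits(wss, "wall_wss")) { T <- T %||% wss$period; wss <- wss$wss }
  if (is.null(T) || !is.finite(T)) stop("tawss: cycle duration T required")
  check_cycle(wss, T)
  periodic_mean(abs(wss))
}

# Periodic trapezoidal mean over columns: samples uniform, wrap-around
# closes the cycle, so this is the plain row mean.
periodic_mean <- function(M) rowMeans(M)

#' Oscillatory shear index
#'
#' \deqn{OSI = \tfrac12\left(1 -
#'   \frac{|\int_0^T WSS\,dt|}{\int_0^T |WSS|\,dt}\right) \in [0, 0.5].}
#' Zero for strictly unidirectional WSS; 0.5 for perfectly balanced
#' reversal.  Stations with identically zero WSS are reported as 0 and
#' flagged in the `undefined` attribute.
#'
#' @inheritParams tawss
#' @return numeric vector of OSI per station, with attribute `undefined`
#' @export
osi <- function(wss, T = NULL) {
  if (inherits(wss, "wall_wss")) { T <- T %||% wss$period; wss <- wss$wss }
  check_cycle(wss, T)
  num <- abs(periodic_mean(wss))
  den <- periodic_mean(abs(wss))
  undef <- den <= 0
  out <- ifelse(undef, 0, 0.5 * (1 - num / pmax(den, 1e-300)))
  out <- pmin(pmax(out, 0), 0.5)
  attr(out, "undefined") <- undef
  out
}

#' Relative residence time
#'
#' \deqn{RRT = \frac{1}{(1 - 2\,OSI)\cdot TAWSS},} a surrogate for the time
#' a particle resides near the endothelium.  `OSI = 0.5` gives `Inf`;
#' `TAWSS = 0` is undefined and flagged.
#'
#' @param tawss TAWSS per station (Pa)
#' @param osi OSI per station
#' @return RRT per station (1/Pa) with attribute `undefined` where TAWSS = 0
#' @export
rrt <- function(tawss, osi) {
  stopifnot(length(tawss) == length(osi))
  undef <- tawss <= 0
  out <- ifelse(undef, NA_real_, 1 / ((1 - 2 * osi) * tawss))
  attr(out, "undefined") <- undef
  out
}

#' HOLMES metric (optional)
#'
#' Combined WSS metric `TAWSS * (0.5 - OSI)`, the standard literature
#' definition (highly oscillatory, low-magnitude shear).  Provenance note:
#' this definition is adopted from the general WSS-metrics literature; it is
#' emitted with attribute `provenance = "literature-definition"`.
#'
#' @inheritParams rrt
#' @return HOLMES per station (Pa)
#' @export
holmes <- function(tawss, osi) {
  stopifnot(length(tawss) == length(osi))
  structure(tawss * (0.5 - osi), provenance = "literature-definition")
}

#' Compute FFR from a transient solution
#'
#' `Pa` is the area-averaged pressure at the inlet cross-section, `Pd` the
#' area-averaged pressure at the virtual wire station, placed `wire_offset`
#' millimetres distal to the stenosis throat (clinically the wire sits 2-3 cm
#' beyond the lesion).  The canonical FFR is the ratio of cycle-averaged
#' pressures; the instantaneous trace `ffr_t` is also returned
#' (`time_spec = "instant"` with `instant_index` selects a single stored
#' step instead).
#'
#' @param history a [solve_transient()] result
#' @param stenosis a [compute_beta_profile()] report locating the throat
#' @param wire_offset distance from throat to wire (mm); clipped to 90% of
#'   the remaining vessel with a warning
#' @param time_spec `"cycle-average"` (default) or `"instant"`
#' @param instant_index stored-step index used when `time_spec = "instant"`
#' @return object of class `ffr_result`: `Pa`, `Pd` (mmHg), `ffr`, `s_wire`,
#'   `ffr_t` (instantaneous trace)
#' @export
compute_ffr <- function(history, stenosis, wire_offset = 20,
                        time_spec = c("cycle-average", "instant"),
                        instant_index = NULL) {
  time_spec <- match.arg(time_spec)
  grid <- history$grid
  s_cells <- (grid$s_nodes[-1L] + grid$s_nodes[-length(grid$s_nodes)]) / 2
  s_throat <- if (!is.null(stenosis)) stenosis$s_min else s_cells[which.min(grid$r_wall)]
  s_wire <- s_throat + wire_offset
  s_max <- max(s_cells)
  if (s_wire > s_max) {
    s_clip <- s_throat + 0.9 * (s_max - s_throat)
    if (s_clip <= s_throat)
      stop("compute_ffr: wire position beyond the outlet even after clipping")
    warning(sprintf("compute_ffr: wire position %.1f mm clipped to %.1f mm (90%% of remaining length)",
                    s_wire, s_clip))
    s_wire <- s_clip
  }
  iw <- which.min(abs(s_cells - s_wire))
  win <- history$vol[1L, ]; wout <- history$vol[iw, ]
  nt <- dim(history$p)[3]
  Pa_t <- vapply(seq_len(nt), function(k)
    sum(history$p[1L, , k] * win) / sum(win), numeric(1))
  Pd_t <- vapply(seq_len(nt), function(k)
    sum(history$p[iw, , k] * wout) / sum(wout), numeric(1))
  Pa_t <- Pa_to_mmHg(Pa_t); Pd_t <- Pa_to_mmHg(Pd_t)
  if (time_spec == "instant") {
    k <- instant_index %||% which.max(Pa_t)
    Pa <- Pa_t[k]; Pd <- Pd_t[k]
  } else {
    Pa <- mean(Pa_t); Pd <- mean(Pd_t)
  }
  structure(list(Pa = Pa, Pd = Pd, ffr = Pd / Pa, s_wire = s_wire,
                 time_spec = time_spec, ffr_t = Pd_t / Pa_t,
                 Pa_t = Pa_t, Pd_t = Pd_t),
            class = "ffr_result")
}

#' FFR of a steady (method 1) solution
#'
#' @param field a [solve_steady()] `flow_field`
#' @param stenosis optional [compute_beta_profile()] report
#' @param wire_offset distance from throat to wire (mm)
#' @return an `ffr_result`
#' @export
compute_ffr_steady <- function(field, stenosis = NULL, wire_offset = 20) {
  grid <- field$grid
  s_cells <- (grid$s_nodes[-1L] + grid$s_nodes[-length(grid$s_nodes)]) / 2
  s_throat <- if (!is.null(stenosis)) stenosis$s_min else s_cells[which.min(grid$r_wall)]
  s_wire <- min(s_throat + wire_offset, s_throat + 0.9 * (max(s_cells) - s_throat))
  iw <- which.min(abs(s_cells - s_wire))
  Pa <- Pa_to_mmHg(section_pressure(field, 1L))
  Pd <- Pa_to_mmHg(section_pressure(field, iw))
  structure(list(Pa = Pa, Pd = Pd, ffr = Pd / Pa, s_wire = s_wire,
                 time_spec = "steady", ffr_t = Pd / Pa),
            class = "ffr_result")
}

#' @export
print.ffr_result <- function(x, ...) {
  cat(sprintf("FFR = %.4f (Pa = %.2f mmHg, Pd = %.2f mmHg at s = %.1f mm, %s)\n",
              x$ffr, x$Pa, x$Pd, x$s_wire, x$time_spec))
  invisible(x)
}

#' Percentage error between invasive and computed FFR
#'
#' `100 * |invasive - virtual| / invasive`, truncated toward zero to one
#' decimal — the convention of the published comparison tables (0.5618%
#' prints as 0.5, 3.45% as 3.4).
#'
#' @param invasive invasive FFR in (0, 1]
#' @param virtual computed FFR in (0, 1]
#' @return error in percent, one truncated decimal
#' @export
ffr_error <- function(invasive, virtual) {
  if (any(invasive <= 0 | invasive > 1) || any(virtual <= 0 | virtual > 1))
    stop("ffr_error: FFR values must lie in (0, 1]")
  trunc_guard(100 * abs(invasive - virtual) / invasive, 1L)
}

#' Pointwise percentage pressure difference between two solutions
#'
#' `100 * (p_a - p_b) / p_a` per cell at a chosen instant (`"instant"` with
#' `instant_index`) or as a cycle average, for contour rendering of
#' between-methodology differences.  Both solutions must share one grid.
#'
#' @param sol_a,sol_b two `field_history` (or `flow_field`) objects on the
#'   same grid
#' @param time_spec `"cycle-average"` or `"instant"`
#' @param instant_index stored-step index for `"instant"`
#' @return matrix (n_axial x n_radial) of percentage differences
#' @export
pressure_diff_field <- function(sol_a, sol_b,
                                time_spec = c("cycle-average", "instant"),
                                instant_index = NULL) {
  time_spec <- match.arg(time_spec)
  pa <- if (inherits(sol_a, "flow_field")) sol_a$p else {
    if (time_spec == "instant") {
      k <- instant_index %||% dim(sol_a$p)[3]
      sol_a$p[, , k]
    } else apply(sol_a$p, c(1, 2), mean)
  }
  pb <- if (inherits(sol_b, "flow_field")) sol_b$p else {
    if (time_spec == "instant") {
      k <- instant_index %||% dim(sol_b$p)[3]
      sol_b$p[, , k]
    } else apply(sol_b$p, c(1, 2), mean)
  }
  if (!identical(dim(pa), dim(pb)))
    stop("pressure_diff_field: solutions are on different grids")
  100 * (pa - pb) / pa
}

#' Assemble and write the per-station wall-metrics table
#'
#' @param wss a [wall_shear()] result
#' @param include_holmes also compute the optional HOLMES column
#' @return data.frame `s_mm`, `tawss_mmHg`, `osi`, `rrt_per_mmHg`
#'   (and `holmes_mmHg` when requested)
#' @export
wall_metrics <- function(wss, include_holmes = FALSE) {
  ta <- tawss(wss); os <- osi(wss)
  rr <- rrt(ta, os)
  out <- data.frame(s_mm = wss$s_mm,
                    tawss_mmHg = Pa_to_mmHg(ta),
                    osi = as.numeric(os),
                    rrt_per_mmHg = as.numeric(rr) * MMHG_PA)
  if (include_holmes) out$holmes_mmHg <- Pa_to_mmHg(as.numeric(holmes(ta, os)))
  out
}
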