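#' Degree-of-stenosis profile and stenosis localisation
#'
#' Computes \eqn{\beta(s) = 100\,(1 - d(s)/D)} where `d` is the lumen
#' diameter and `D` is the upstream reference diameter: the mean of `d(s)`
#' over a window immediately proximal to the narrowest point, excluding a
#' guard band around the throat.  The throat is the global minimum of the
#' smoothed profile (ties break proximally); \eqn{\beta} itself is evaluated
#' on the unsmoothed diameters so a focal minimum is not flattened twice.
#'
#' @param profile a [measure_diameters()] result (or any `diameter_profile`)
#' @param upstream_window length of the upstream reference window (mm)
#' @param guard guard band excluded between window and throat (mm)
#' @return object of class `stenosis_report`: `s_min`, `d_min`, `D_ref`,
#'   `beta` (vector, %), `beta_max`, plus the input coordinates
#' @export
#' @examples
#' pr <- make_radius_profile(beta_target = 45)
#' dp <- structure(list(s_mm = pr$s, d_mm = 2 * pr$r, mm_per_px = NA),
#'                 class = "diameter_profile")
#' compute_beta_profile(dp)$beta_max     # ~45
compute_beta_profile <- function(profile, upstream_window = 5, guard = 2) {
  stopifnot(inherits(profile, "diameter_profile"))
  s <- profile$s_mm; d <- profile$d_mm
  if (max(s) - min(s) <= upstream_window)
    stop("compute_beta_profile: profile shorter than the upstream window")
  dsm <- smooth_ma(d, 5L)
  if (max(dsm) - min(dsm) <= 1e-12 * mean(dsm)) {
    # uniform tube: no throat; beta is identically zero against the mean
    D <- mean(d)
    return(structure(list(s_min = s[1], d_min = d[1], D_ref = D,
                          beta = pmax(0, 100 * (1 - d / D)), beta_max = 0,
                          s_mm = s, d_mm = d,
                          upstream_window = upstream_window, guard = guard),
                     class = "stenosis_report"))
  }
  i_min <- which.min(dsm)                    # ties -> proximal (first)
  s_min <- s[i_min]
  win <- s >= s_min - guard - upstream_window & s < s_min - guard
  if (!any(win))
    stop("compute_beta_profile: narrowest point lies within the upstream window; no proximal reference")
  D <- mean(d[win])
  beta <- pmax(0, 100 * (1 - d / D))
  structure(list(s_min = s_min, d_min = d[i_min], D_ref = D,
                 beta = beta, beta_max = beta[i_min],
                 s_mm = s, d_mm = d,
                 upstream_window = upstream_window, guard = guard),
            class = "stenosis_report")
}

#' @export
print.stenosis_report <- function(x, ...) {
  cat(sprintf("stenosis_report: throat at s = %.2f mm, d = %.3f mm, D = %.3f mm, beta_max = %.1f%%\n",
              x$s_min, x$d_min, x$D_ref, x$beta_max))
  invisible(x)
}

#' Write a stenosis report as CSV
#' @param report a `stenosis_report`
#' @param file path
#' @export
write_stenosis_csv <- function(report, file) {
  write.csv(data.frame(s_mm = report$s_mm, d_mm = report$d_mm,
                       beta_pct = report$beta),
            file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Linear trend of the diameter-versus-length diagram
#'
#' Ordinary least-squares line through `(s, d)`; the slope summarises the
#' diameter taper from upstream to downstream.
#'
#' @param profile a `diameter_profile`
#' @return named numeric vector `c(slope, intercept)` (mm/mm, mm)
#' @export
fit_diameter_trend <- function(profile) {
  stopifnot(inherits(profile, "diameter_profile"),
            length(profile$s_mm) >= 2L)
  fit <- lm(d ~ s, data = data.frame(s = profile$s_mm, d = profile$d_mm))
  c(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
}

#' Revolve a diameter profile into a triangulated lumen surface
#'
#' Edge-to-edge revolution of `r(s) = d(s)/2` about the straightened
#' centerline (the x axis), producing a closed-side triangulated tube for
#' visualisation and export (see [write_vtk_polydata()], [write_stl()]).
#'
#' @param profile a `diameter_profile`
#' @param n_theta number of circumferential divisions (>= 8)
#' @return object of class `revolved_surface`: `vertices` (n x 3, mm),
#'   `faces` (m x 3, 1-based vertex indices), consistent outward normals
#' @export
revolve_surface <- function(profile, n_theta = 32L) {
  stopifnot(inherits(profile, "diameter_profile"), n_theta >= 8L)
  s <- profile$s_mm; r <- profile$d_mm / 2
  ns <- length(s)
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[seq_len(n_theta)]
  verts <- cbind(x = rep(s, each = n_theta),
                 y = rep(r, each = n_theta) * cos(th),
                 z = rep(r, each = n_theta) * sin(th))
  vid <- function(i, j) (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  faces <- matrix(0L, 2L * (ns - 1L) * n_theta, 3L)
  k <- 0L
  for (i in seq_len(ns - 1L)) for (j in seq_len(n_theta)) {
    a <- vid(i, j); b <- vid(i + 1L, j); c2 <- vid(i + 1L, j + 1L); d2 <- vid(i, j + 1L)
    faces[k + 1L, ] <- c(a, b, c2)     # outward-consistent winding
    faces[k + 2L, ] <- c(a, c2, d2)
    k <- k + 2L
  }
  structure(list(vertices = verts, faces = faces, n_theta = n_theta,
                 s_mm = s, r_mm = r),
            class = "revolved_surface")
}

#' Lateral surface area of a revolved surface (sum of triangle areas)
#' @param surface a [revolve_surface()] result
#' @return area in mm^2
#' @export
surface_area <- function(surface) {
  v <- surface$vertices; f <- surface$faces
  a <- v[f[, 2], ] - v[f[, 1], ]; b <- v[f[, 3], ] - v[f[, 1], ]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Build the boundary-layer-graded axisymmetric grid
#'
#' Structured `(s, r)` grid over the lumen: `n_radial_core` uniform core
#' cells plus `bl_layers` wall layers whose thicknesses form a geometric
#' sequence with the given `growth` ratio (finest layer at the wall), all
#' scaled so the outermost node sits exactly on `r(s)` at every station.
#' Axial stations are optionally clustered around the stenosis throat.
#'
#' @param profile a `diameter_profile`
#' @param n_axial number of axial cells (>= 10)
#' @param n_radial_core number of uniform core cells (>= 4)
#' @param bl_layers number of wall boundary layers
#' @param growth geometric growth ratio of the layer thicknesses
#' @param bl_fraction fraction of the local radius occupied by the boundary
#'   layers (0 < bl_fraction < 1)
#' @param refine_near_stenosis cluster axial spacing around the throat
#' @param cluster_strength density contrast of the clustering (>= 0)
#' @param cluster_sigma Gaussian width of the clustering (mm); default 3
#' @return object of class `vessel_grid`: node matrices `Z`, `R`
#'   ((n_axial+1) x (n_radial+1), mm), `eta` radial node fractions,
#'   `s_nodes`, `r_wall`, `bl_layers`, `growth`, `n_cells`
#' @export
build_grid <- function(profile, n_axial = 120L, n_radial_core = 8L,
                       bl_layers = 7L, growth = 1.1, bl_fraction = 0.35,
                       refine_near_stenosis = TRUE, cluster_strength = 2,
                       cluster_sigma = 3) {
  stopifnot(inherits(profile, "diameter_profile"),
            n_axial >= 10L, n_radial_core >= 4L, bl_layers >= 1L, growth >= 1)
  if (!(bl_fraction > 0 && bl_fraction < 1))
    stop("build_grid: first-layer thickness would exceed the local radius; need 0 < bl_fraction < 1")
  s <- profile$s_mm; r <- profile$d_mm / 2
  # axial stations (optionally clustered around the smoothed minimum)
  if (refine_near_stenosis && cluster_strength > 0) {
    s0 <- s[which.min(smooth_ma(profile$d_mm, 5L))]
    fine <- seq(min(s), max(s), length.out = 4096L)
    dens <- 1 + cluster_strength * exp(-(fine - s0)^2 / (2 * cluster_sigma^2))
    cdf <- cumsum(dens); cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
    targets <- seq(0, 1, length.out = n_axial + 1L)
    s_nodes <- approx(cdf, fine, xout = targets, ties = "ordered")$y
    s_nodes[1] <- min(s); s_nodes[n_axial + 1L] <- max(s)
  } else {
    s_nodes <- seq(min(s), max(s), length.out = n_axial + 1L)
  }
  r_wall <- approx(s, r, xout = s_nodes)$y
  # radial node fractions: uniform core then geometric layers, wall finest
  t1 <- bl_fraction * (growth - 1) / (growth^bl_layers - 1)
  layer_t <- t1 * growth^((bl_layers - 1L):0L)       # core-side first
  eta <- c(seq(0, 1 - bl_fraction, length.out = n_radial_core + 1L),
           (1 - bl_fraction) + cumsum(layer_t))
  eta[length(eta)] <- 1                              # exact wall node
  n_radial <- n_radial_core + bl_layers
  Z <- matrix(s_nodes, n_axial + 1L, n_radial + 1L)
  R <- outer(r_wall, eta)
  structure(list(Z = Z, R = R, eta = eta, s_nodes = s_nodes, r_wall = r_wall,
                 bl_layers = as.integer(bl_layers), growth = growth,
                 bl_fraction = bl_fraction,
                 n_axial = as.integer(n_axial), n_radial = as.integer(n_radial),
                 n_cells = as.integer(n_axial) * as.integer(n_radial)),
            class = "vessel_grid")
}

#' @export
print.vessel_grid <- function(x, ...) {
  cat(sprintf("vessel_grid: %d x %d cells (%d total), %d wall layers, growth %.2f\n",
              x$n_axial, x$n_radial, x$n_cells, x$bl_layers, x$growth))
  invisible(x)
}

#' Grid-sensitivity study of the computed FFR
#'
#' Runs the same case (geometry, rheology, boundary conditions, simulation
#' config) on successively refined grids and reports the absolute FFR
#' difference between consecutive levels as a percentage of the finer value.
#' Non-converged levels are flagged and excluded from the differences.
#'
#' @param case list with elements `profile` (a `diameter_profile`),
#'   `rheology`, `bc` (a [assemble_bc()] spec) and `cfg` ([sim_config()])
#' @param levels list of [build_grid()] grids, non-decreasing cell count
#'   (identical levels are allowed and report a 0% difference)
#' @return object of class `convergence_report`: data.frame with per-level
#'   cell counts, FFR, convergence flag, and between-level differences (%)
#' @export
convergence_study <- function(case, levels) {
  stopifnot(length(levels) >= 2L)
  counts <- vapply(levels, `[[`, integer(1), "n_cells")
  if (any(diff(counts) < 0))
    stop("convergence_study: levels must be ordered coarse to fine")
  res <- lapply(levels, function(g) {
    if (case$bc$method == 1L) {
      fld <- solve_steady(g, case$rheology, case$bc, case$cfg)
      list(ffr = compute_ffr_steady(fld, case$stenosis %||% NULL)$ffr,
           converged = isTRUE(fld$converged))
    } else {
      hist <- solve_transient(g, case$rheology, case$bc, case$cfg)
      list(ffr = compute_ffr(hist, case$stenosis %||% NULL)$ffr,
           converged = isTRUE(hist$converged))
    }
  })
  ffr <- vapply(res, `[[`, numeric(1), "ffr")
  conv <- vapply(res, `[[`, logical(1), "converged")
  if (any(!conv))
    warning("convergence_study: level(s) ", paste(which(!conv), collapse = ", "),
            " did not converge; excluded from differences")
  dif <- rep(NA_real_, length(levels) - 1L)
  for (k in seq_len(length(levels) - 1L)) {
    if (conv[k] && conv[k + 1L])
      dif[k] <- 100 * abs(ffr[k + 1L] - ffr[k]) / ffr[k + 1L]
  }
  structure(list(cells = counts, ffr = ffr, converged = conv,
                 diff_pct = dif),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("Grid sensitivity:\n")
  for (i in seq_along(x$cells)) {
    cat(sprintf("  level %d: %6d cells, FFR = %.4f%s\n", i, x$cells[i],
                x$ffr[i], if (x$converged[i]) "" else "  (not converged)"))
  }
  cat("  between-level |dFFR|:",
      paste(sprintf("%.3g%%", x$diff_pct), collapse = ", "), "\n")
  invisible(x)
}
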