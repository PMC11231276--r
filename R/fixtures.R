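#' Ground-truth lumen radius profile with a Gaussian stenosis
#'
#' Generates the analytic radius profile
#' \deqn{r(s) = r_0\,\bigl(1 - \tfrac{\beta_t}{100}
#'   e^{-(s-c)^2/(2w^2)}\bigr)}
#' whose degree of stenosis (diameter ratio against the upstream reference)
#' equals `beta_target` at the throat `s = c`.  This is the ground truth that
#' the segmentation and stenosis-quantification stages are tested against.
#'
#' Defaults describe a focal intermediate lesion in a proximal LAD-like
#' vessel: 30 mm segment, 1.5 mm healthy radius, throat mid-segment,
#' Gaussian half-width 0.9 mm (lesion roughly 3.5 mm long).
#'
#' @param L vessel length (mm)
#' @param r0 healthy lumen radius (mm)
#' @param c stenosis centre (mm), `0 < c < L`
#' @param beta_target degree of stenosis (%), `0 <= beta_target < 100`
#' @param w Gaussian half-width of the narrowing (mm)
#' @param step arclength sampling step (mm)
#' @return object of class `radius_profile` with fields `s`, `r` (mm), `step`
#' @export
#' @examples
#' pr <- make_radius_profile(beta_target = 45)
#' min(pr$r)          # 1.5 * 0.55 = 0.825 mm at the throat
make_radius_profile <- function(L = 30, r0 = 1.5, c = L / 2,
                                beta_target = 32, w = 0.9, step = 0.05) {
  if (beta_target < 0 || beta_target >= 100)
    stop("make_radius_profile: beta_target must be in [0, 100); 100 closes the lumen")
  if (!(c > 0 && c < L)) stop("make_radius_profile: need 0 < c < L")
  stopifnot(r0 > 0, w > 0, step > 0)
  s <- seq(0, L, by = step)
  r <- r0 * (1 - beta_target / 100 * exp(-(s - c)^2 / (2 * w^2)))
  structure(list(s = s, r = r, step = step,
                 truth = list(L = L, r0 = r0, c = c,
                              beta_target = beta_target, w = w)),
            class = "radius_profile")
}

#' Convert a ground-truth radius profile to a diameter profile
#'
#' Convenience bridge between the synthetic generator and the geometry /
#' solver stages (which consume measured `diameter_profile` objects):
#' `d(s) = 2 r(s)`.
#'
#' @param profile a [make_radius_profile()]
#' @return a `diameter_profile`
#' @export
as_diameter_profile <- function(profile) {
  stopifnot(inherits(profile, "radius_profile"))
  structure(list(s_mm = profile$s, d_mm = 2 * profile$r,
                 mm_per_px = NA_real_),
            class = "diameter_profile")
}

#' @export
print.radius_profile <- function(x, ...) {
  cat(sprintf("radius_profile: L = %g mm, %d samples, r in [%.3f, %.3f] mm\n",
              max(x$s), length(x$s), min(x$r), max(x$r)))
  invisible(x)
}

#' Imaging parameters for the synthetic angiogram renderer
#'
#' Mono-energetic contrast model: pixel intensity is the background level
#' minus an attenuation proportional to the contrast path length (the lumen
#' chord at that pixel), plus optional Gaussian noise, clipped to the bit
#' depth.
#'
#' @param mm_per_px pixel calibration (mm/pixel), > 0
#' @param I_bg background grey level, within the bit depth
#' @param A attenuation (grey levels per mm of contrast path)
#' @param noise_sd additive Gaussian noise standard deviation (grey levels)
#' @param size image size `c(rows, cols)` in pixels
#' @param bits bit depth (8 or 16)
#' @return object of class `imaging_params`
#' @export
imaging_params <- function(mm_per_px = 0.08, I_bg = 58000, A = 12000,
                           noise_sd = 0, size = c(128L, 416L), bits = 16L) {
  stopifnot(mm_per_px > 0, noise_sd >= 0, length(size) == 2L, bits %in% c(8L, 16L))
  if (I_bg < 0 || I_bg > 2^bits - 1)
    stop("imaging_params: I_bg outside the bit depth")
  structure(list(mm_per_px = mm_per_px, I_bg = I_bg, A = A,
                 noise_sd = noise_sd, size = as.integer(size),
                 bits = as.integer(bits)),
            class = "imaging_params")
}

#' Render a synthetic angiographic cine of a contrast-filled vessel
#'
#' Draws the vessel described by `profile` into `n_frames` grey-level frames.
#' The per-pixel intensity is `I_bg - A * chord * contrast(frame) + noise`,
#' where `chord = 2*sqrt(r^2 - d^2)` is the contrast path length at
#' perpendicular offset `d` from the centerline, and the contrast filling
#' factor peaks (is 1) at `ed_frame` — so the end-diastolic frame is the
#' darkest.  The vessel is horizontal by default; `curve_amp_mm` bends the
#' centerline into a gentle sinusoid (small-slope rendering) to exercise
#' centerline extraction.
#'
#' Identical `seed` and parameters give bit-identical cines, and the exact
#' ground truth used is attached as the `truth` element.
#'
#' @param profile a [make_radius_profile()]
#' @param imaging an [imaging_params()]
#' @param n_frames number of frames
#' @param ed_frame index (1-based) of the maximally opacified end-diastolic
#'   frame
#' @param seed RNG seed (mandatory when `noise_sd > 0`)
#' @param curve_amp_mm amplitude of the optional sinusoidal centerline bend
#'   (mm); 0 keeps the vessel straight
#' @param curve_wavelength_mm wavelength of the bend (mm)
#' @return object of class `cine`: list of frame matrices plus metadata
#' @export
render_cine <- function(profile, imaging = imaging_params(), n_frames = 12L,
                        ed_frame = 6L, seed = 1L,
                        curve_amp_mm = 0, curve_wavelength_mm = 40) {
  stopifnot(inherits(profile, "radius_profile"), inherits(imaging, "imaging_params"))
  if (ed_frame < 1L || ed_frame > n_frames)
    stop("render_cine: ed_frame out of range")
  nr <- imaging$size[1]; nc <- imaging$size[2]
  px <- imaging$mm_per_px
  L <- max(profile$s)
  need_rows <- (2 * max(profile$r) + 2 * curve_amp_mm) / px + 4
  if (L / px + 4 > nc || need_rows > nr)
    stop("render_cine: vessel wider than image; enlarge size or coarsen mm_per_px")
  x0 <- (nc - L / px) / 2                       # first column of the vessel
  col_mm <- ((seq_len(nc)) - x0) * px           # arclength coordinate per column
  inside <- col_mm >= 0 & col_mm <= L
  r_col <- rep(0, nc)
  r_col[inside] <- approx(profile$s, profile$r, xout = col_mm[inside])$y
  yc_mm <- rep((nr / 2) * px, nc) +
    if (curve_amp_mm > 0)
      curve_amp_mm * sin(2 * pi * col_mm / curve_wavelength_mm) else 0
  slope <- if (curve_amp_mm > 0)
    curve_amp_mm * 2 * pi / curve_wavelength_mm *
      cos(2 * pi * col_mm / curve_wavelength_mm) else rep(0, nc)
  costh <- 1 / sqrt(1 + slope^2)
  row_mm <- seq_len(nr) * px
  # chord matrix (rows x cols): perpendicular offset via the small-slope
  # approximation d = (y - yc)*cos(theta)
  dperp <- (outer(row_mm, yc_mm, `-`)) * matrix(costh, nr, nc, byrow = TRUE)
  r_mat <- matrix(r_col, nr, nc, byrow = TRUE)
  chord2 <- r_mat^2 - dperp^2
  chord <- ifelse(chord2 > 0, 2 * sqrt(pmax(chord2, 0)), 0)

  k <- seq_len(n_frames)
  contrast <- 0.55 + 0.45 * exp(2 * (cos(2 * pi * (k - ed_frame) / n_frames) - 1))
  vmax <- 2^imaging$bits - 1
  frames <- with_seed(seed, lapply(k, function(i) {
    I <- imaging$I_bg - imaging$A * chord * contrast[i]
    if (imaging$noise_sd > 0)
      I <- I + matrix(rnorm(nr * nc, sd = imaging$noise_sd), nr, nc)
    round(pmin(pmax(I, 0), vmax))
  }))
  structure(list(frames = frames, imaging = imaging,
                 ed_frame = as.integer(ed_frame), n_frames = as.integer(n_frames),
                 normalized = FALSE,
                 truth = list(profile = profile, x0_px = x0,
                              yc_mm = yc_mm, contrast = contrast,
                              curve_amp_mm = curve_amp_mm,
                              curve_wavelength_mm = curve_wavelength_mm,
                              seed = seed)),
            class = "cine")
}

#' @export
print.cine <- function(x, ...) {
  cat(sprintf("cine: %d frames of %d x %d px (%.3g mm/px), ed_frame = %d%s\n",
              x$n_frames, x$imaging$size[1], x$imaging$size[2],
              x$imaging$mm_per_px, x$ed_frame,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Generate a distal pressure trace from known Windkessel parameters
#'
#' Drives the three-element Windkessel ODE with a periodic flow wave until a
#' periodic state and returns the distal pressure — ground truth for
#' [wk3_fit()] recovery tests.  The parameters used are attached as the
#' `truth` attribute.
#'
#' @param Q a [flow_wave()] (ml/s)
#' @param params [wk3_params()]
#' @param T optional period override (defaults to `Q$period`)
#' @param dt integration step (s)
#' @param noise_sd multiplicative Gaussian noise sd (relative, e.g. 0.02);
#'   0 keeps the trace exact
#' @param seed RNG seed used when `noise_sd > 0`
#' @return a [pressure_wave()] with attribute `truth`
#' @export
make_distal_trace <- function(Q, params, T = Q$period, dt = T / 500,
                              noise_sd = 0, seed = 1L) {
  stopifnot(inherits(Q, "flow_wave"))
  if (abs(T - Q$period) > 1e-12 * T)
    stop("make_distal_trace: Q must be periodic with period T")
  pw <- wk3_solve(Q, params, dt = dt, n_periods = 60L)
  if (noise_sd > 0)
    pw$p <- with_seed(seed, pw$p * (1 + rnorm(length(pw$p), sd = noise_sd)))
  attr(pw, "truth") <- list(params = params, noise_sd = noise_sd, seed = seed)
  pw
}

#' Write / read a cine as numbered 16-bit TIFF frames plus JSON sidecar
#'
#' Frames are written as `frame_###.tif` (grey, 16-bit by default) and the
#' metadata (`mm_per_px`, `ed_frame`, bit depth, frame count) as
#' `cine_meta.json`.
#'
#' @param cine a [render_cine()] object
#' @param dir output directory (created if absent)
#' @return `write_cine` returns `dir` invisibly; `read_cine` returns a `cine`
#'   (without ground-truth attachment).
#' @export
write_cine <- function(cine, dir) {
  stopifnot(inherits(cine, "cine"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vmax <- 2^cine$imaging$bits - 1
  for (i in seq_len(cine$n_frames)) {
    tiff::writeTIFF(cine$frames[[i]] / vmax,
                    file.path(dir, sprintf("frame_%03d.tif", i)),
                    bits.per.sample = cine$imaging$bits)
  }
  meta <- list(mm_per_px = cine$imaging$mm_per_px, ed_frame = cine$ed_frame,
               n_frames = cine$n_frames, bits = cine$imaging$bits,
               I_bg = cine$imaging$I_bg, normalized = cine$normalized)
  jsonlite::write_json(meta, file.path(dir, "cine_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cine
#' @export
read_cine <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cine_meta.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.(tif|tiff|png)$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("read_cine: no frame files found in ", dir)
  vmax <- 2^meta$bits - 1
  frames <- lapply(files, function(f) {
    img <- if (grepl("png$", f)) png::readPNG(f) else tiff::readTIFF(f)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    round(img * vmax)
  })
  imaging <- imaging_params(mm_per_px = meta$mm_per_px, I_bg = meta$I_bg,
                            A = 1, noise_sd = 0, size = dim(frames[[1]]),
                            bits = meta$bits)
  structure(list(frames = frames, imaging = imaging,
                 ed_frame = as.integer(meta$ed_frame),
                 n_frames = length(frames),
                 normalized = isTRUE(meta$normalized), truth = NULL),
            class = "cine")
}
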