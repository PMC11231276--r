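#' Normalise a cine to a common [0, 1] intensity range
#'
#' All frames are rescaled by one affine map computed from the global
#' intensity range of the whole cine (so per-frame pixel ordering, and
#' ordering between frames, is preserved exactly).
#'
#' @param cine a [render_cine()] object (or one read with [read_cine()])
#' @return the cine with frames in `[0, 1]` and `normalized = TRUE`
#' @export
normalize_cine <- function(cine) {
  stopifnot(inherits(cine, "cine"), cine$n_frames >= 1L)
  lo <- min(vapply(cine$frames, min, numeric(1)))
  hi <- max(vapply(cine$frames, max, numeric(1)))
  if (hi - lo < 1e-12)
    stop("normalize_cine: cine has zero dynamic range")
  cine$frames <- lapply(cine$frames, function(f) (f - lo) / (hi - lo))
  cine$normalized <- TRUE
  cine$norm_range <- c(lo, hi)
  cine
}

#' Pick the end-diastolic (maximally opacified) frame
#'
#' Contrast filling makes the vessel darkest at end diastole, so the selected
#' frame minimises the mean intensity over a vessel-candidate region (dark
#' pixels of the temporal-minimum image).  Ties break to the lowest index.
#'
#' @param cine a (preferably normalised) cine
#' @return 1-based frame index
#' @export
select_end_diastolic_frame <- function(cine) {
  stopifnot(inherits(cine, "cine"), cine$n_frames >= 1L)
  if (cine$n_frames == 1L) return(1L)
  tmin <- Reduce(pmin, cine$frames)
  med <- median(tmin)
  cand <- tmin <= med - 0.25 * (med - min(tmin))
  if (!any(cand)) cand <- tmin <= med
  means <- vapply(cine$frames, function(f) mean(f[cand]), numeric(1))
  which.min(means)          # ties -> lowest index
}

#' Extract one frame of a cine
#' @param cine a cine
#' @param i frame index (default: the end-diastolic frame)
#' @return intensity matrix
#' @export
get_frame <- function(cine, i = NULL) {
  if (is.null(i)) i <- select_end_diastolic_frame(cine)
  cine$frames[[i]]
}

#' Segment the contrast-filled lumen of one frame
#'
#' Thresholds a normalised frame (vessel darker than background), keeps the
#' largest connected component and fills holes.  The default threshold rule
#' is fractional-depth: background level (frame median) minus `f` times the
#' global dynamic depth, which keeps the detected boundary within a pixel of
#' the true lumen edge on contrast-chord images.  `method = "otsu"` and a
#' fixed numeric threshold are available as overrides.
#'
#' @param frame normalised intensity matrix in `[0, 1]`
#' @param threshold_cfg list with `method` (`"fraction"`, `"otsu"` or
#'   `"fixed"`), `f` (fraction of dynamic depth, default 0.15) and `value`
#'   (for `"fixed"`)
#' @param invert set `TRUE` for bright-vessel polarity
#' @param frame_index provenance index stored in the result
#' @return object of class `lumen_mask` with fields `mask`, `threshold`,
#'   `frame_index`, `degenerate`
#' @export
segment_lumen <- function(frame, threshold_cfg = list(method = "fraction", f = 0.15),
                          invert = FALSE, frame_index = NA_integer_) {
  stopifnot(is.matrix(frame))
  if (invert) frame <- max(frame) + min(frame) - frame
  method <- threshold_cfg$method %||% "fraction"
  thr <- switch(method,
    fixed = threshold_cfg$value,
    otsu = EBImage::otsu(EBImage::Image(pmin(pmax(frame, 0), 1)),
                         range = c(0, 1)),
    fraction = {
      f <- threshold_cfg$f %||% 0.15
      bg <- median(frame)
      bg - f * (bg - min(frame))
    },
    stop("segment_lumen: unknown threshold method ", method))
  raw <- frame < thr
  if (!any(raw))
    stop("segment_lumen: no vessel found (threshold below all intensities)")
  degenerate <- all(raw)
  mask <- largest_component(raw)
  mask <- EBImage::fillHull(mask * 1L) > 0
  structure(list(mask = mask, threshold = as.numeric(thr),
                 frame_index = frame_index, degenerate = degenerate),
            class = "lumen_mask")
}

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1L)
  n <- max(lab)
  if (n == 0L) stop("largest_component: empty mask")
  if (n == 1L) return(lab == 1)
  sizes <- tabulate(lab[lab > 0], nbins = n)
  lab == which.max(sizes)
}

#' @export
print.lumen_mask <- function(x, ...) {
  cat(sprintf("lumen_mask: %d px (threshold %.4g%s)\n",
              sum(x$mask), x$threshold,
              if (x$degenerate) ", DEGENERATE: threshold above all intensities" else ""))
  invisible(x)
}

# Skeletonise a mask and build its pixel graph (8-connectivity, Euclidean
# edge weights).  Shared by centerline extraction and branch pruning.
skeleton_graph <- function(mask) {
  skel <- cpp_thin(mask)
  idx <- which(skel, arr.ind = TRUE)
  n <- nrow(idx)
  if (n < 2L) stop("skeleton_graph: skeleton has fewer than 2 pixels")
  idmat <- matrix(0L, nrow(mask), ncol(mask))
  idmat[skel] <- seq_len(n)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- idx[, 1] + dr; cc <- idx[, 2] + dc
    ok <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
    nb <- integer(n); nb[ok] <- idmat[cbind(rr[ok], cc[ok])]
    sel <- ok & nb > seq_len(n)          # each undirected edge once
    from <- c(from, which(sel)); to <- c(to, nb[sel])
    w <- c(w, rep(sqrt(dr^2 + dc^2), sum(sel)))
  }
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  igraph::E(g)$weight <- w
  deg <- igraph::degree(g)
  list(skel = skel, idx = idx, g = g, endpoints = which(deg == 1))
}

# Longest endpoint-to-endpoint geodesic through the skeleton graph;
# returns ordered pixel indices (rows of sg$idx).
skeleton_main_path <- function(sg, score = NULL) {
  ep <- sg$endpoints
  if (length(ep) < 2L)
    stop("extract_centerline: skeleton is cyclic with no unambiguous longest path; ",
         "endpoint candidates: ", paste(ep, collapse = ", "))
  D <- igraph::distances(sg$g, v = ep, to = ep)
  D[!is.finite(D)] <- -Inf
  best <- which(D == max(D), arr.ind = TRUE)[1, ]
  path <- igraph::shortest_paths(sg$g, from = ep[best[1]], to = ep[best[2]],
                                 output = "vpath")$vpath[[1]]
  as.integer(path)
}

#' Extract the vessel centerline from a lumen mask
#'
#' Thins the mask to a 1-px skeleton, takes the longest endpoint-to-endpoint
#' geodesic through the skeleton graph, orients it inlet (leftmost end by
#' default) to outlet, smooths it with a moving average and computes the
#' cumulative arclength from the pixel spacing.
#'
#' @param mask a [segment_lumen()] result (or plain logical matrix)
#' @param mm_per_px pixel calibration (mm)
#' @param smooth moving-average window (samples); 5 suppresses pixelation
#'   without erasing a focal stenosis
#' @param inlet `"left"` or `"right"`: which image side is the inlet
#' @param trim_ends drop path samples within one local half-width of each
#'   skeleton endpoint (the skeleton of a blunt-ended vessel grows unreliable
#'   tails toward the corners)
#' @param refine recentre each sample to the perpendicular midpoint of the
#'   mask (suppresses sub-pixel thinning wobble on slanted vessels)
#' @return object of class `centerline`: `rc` (n x 2 matrix of row/col pixel
#'   coordinates), `s_mm` (strictly increasing arclength), `mm_per_px`
#' @export
extract_centerline <- function(mask, mm_per_px, smooth = 5L, inlet = "left",
                               trim_ends = TRUE, refine = TRUE) {
  m <- if (inherits(mask, "lumen_mask")) mask$mask else mask
  sg <- skeleton_graph(m)
  path <- skeleton_main_path(sg)
  rc <- sg$idx[path, , drop = FALSE]
  if (trim_ends && nrow(rc) > 12L) {
    dm <- EBImage::distmap(m * 1L)
    halfw <- median(dm[rc])
    k <- max(0L, min(round(halfw) - 1L, nrow(rc) %/% 6L))
    if (k > 0L) rc <- rc[(k + 1L):(nrow(rc) - k), , drop = FALSE]
  }
  flip <- switch(match.arg(inlet, c("left", "right")),
                 left = rc[1, 2] > rc[nrow(rc), 2],
                 right = rc[1, 2] < rc[nrow(rc), 2])
  if (flip) rc <- rc[rev(seq_len(nrow(rc))), , drop = FALSE]
  rs <- smooth_ma(rc[, 1], smooth)
  cs <- smooth_ma(rc[, 2], smooth)
  if (refine) {
    # one medial-refinement pass: move each sample to the midpoint of the
    # mask extent along the local perpendicular (the raw skeleton can wobble
    # a pixel off-centre on slanted vessels)
    mid <- mask_midpoints(m, rs, cs)
    rs <- smooth_ma(mid$r, smooth)
    cs <- smooth_ma(mid$c, smooth)
  }
  s_mm <- cumsum(c(0, sqrt(diff(rs)^2 + diff(cs)^2))) * mm_per_px
  structure(list(rc = cbind(row = rs, col = cs), s_mm = s_mm,
                 mm_per_px = mm_per_px),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("centerline: %d samples, arclength %.2f mm\n",
              nrow(x$rc), max(x$s_mm)))
  invisible(x)
}

#' Remove side branches, keeping the widest continuous path
#'
#' Scores every endpoint-to-endpoint skeleton path by its cumulative lumen
#' half-width (distance-transform values along the path) and keeps the
#' highest-scoring one; the mask is rebuilt as the union of the inscribed
#' disks along that path, so main-path diameters change by at most a pixel.
#' When the two best paths have indistinguishable widths the longer one is
#' retained and a warning is emitted.
#'
#' @param mask a [segment_lumen()] result or logical matrix
#' @return pruned mask of the same class as the input
#' @export
prune_side_branches <- function(mask) {
  obj <- if (inherits(mask, "lumen_mask")) mask else NULL
  m <- if (is.null(obj)) mask else obj$mask
  sg <- skeleton_graph(m)
  ep <- sg$endpoints
  if (length(ep) <= 2L) return(mask)          # branch-free: identity
  dm <- as.numeric(EBImage::distmap(m * 1L))
  dim(dm) <- dim(m)
  pairs <- utils::combn(ep, 2L)
  paths <- lapply(seq_len(ncol(pairs)), function(k)
    igraph::shortest_paths(sg$g, from = pairs[1, k], to = pairs[2, k],
                           output = "vpath")$vpath[[1]])
  score <- vapply(paths, function(p)
    sum(dm[sg$idx[as.integer(p), , drop = FALSE]]), numeric(1))
  meanw <- vapply(paths, function(p)
    mean(dm[sg$idx[as.integer(p), , drop = FALSE]]), numeric(1))
  plen <- vapply(paths, length, integer(1))
  ord <- order(-score, -plen)
  bi <- ord[1]
  if (length(ord) > 1L && abs(meanw[bi] - meanw[ord[2]]) < 0.25)
    warning("prune_side_branches: branches of indistinguishable width; keeping the longer path")
  keep <- sg$idx[as.integer(paths[[bi]]), , drop = FALSE]
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (k in seq_len(nrow(keep))) {
    r0 <- keep[k, 1]; c0 <- keep[k, 2]
    rad <- dm[r0, c0]
    ir <- max(1, ceiling(r0 - rad)):min(nrow(m), floor(r0 + rad))
    ic <- max(1, ceiling(c0 - rad)):min(ncol(m), floor(c0 + rad))
    d2 <- outer((ir - r0)^2, (ic - c0)^2, `+`)
    out[ir, ic] <- out[ir, ic] | (d2 < rad^2 - 1e-9)
  }
  out <- out & m
  out <- EBImage::fillHull(largest_component(out) * 1L) > 0
  if (is.null(obj)) return(out)
  obj$mask <- out
  obj
}

# Midpoint of the mask extent along the local perpendicular at each
# polyline sample; keeps the original sample where a ray leaves the image.
mask_midpoints <- function(m, rs, cs) {
  n <- length(rs)
  tr <- c(rs[2] - rs[1], (rs[3:n] - rs[1:(n - 2)]) / 2, rs[n] - rs[n - 1])
  tc <- c(cs[2] - cs[1], (cs[3:n] - cs[1:(n - 2)]) / 2, cs[n] - cs[n - 1])
  tl <- sqrt(tr^2 + tc^2); tl[tl == 0] <- 1
  nr_ <- -tc / tl; nc_ <- tr / tl
  step <- 0.25
  out_r <- rs; out_c <- cs
  for (i in seq_len(n)) {
    h <- c(NA_real_, NA_real_)
    for (sgn in c(1, -1)) {
      k <- 0
      repeat {
        k <- k + 1
        r <- rs[i] + sgn * k * step * nr_[i]
        c2 <- cs[i] + sgn * k * step * nc_[i]
        if (r < 1 || r > nrow(m) || c2 < 1 || c2 > ncol(m)) { k <- NA; break }
        if (!m[round(r), round(c2)]) break
      }
      h[(3 - sgn) / 2] <- if (is.na(k)) NA_real_ else (k - 0.5) * step
    }
    if (!anyNA(h)) {
      off <- (h[1] - h[2]) / 2
      out_r[i] <- rs[i] + off * nr_[i]
      out_c[i] <- cs[i] + off * nc_[i]
    }
  }
  list(r = out_r, c = out_c)
}

bilinear <- function(M, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  r0 <- pmin(pmax(r0, 1), nrow(M) - 1L); c0 <- pmin(pmax(c0, 1), ncol(M) - 1L)
  fr <- r - r0; fc <- c - c0
  M[cbind(r0, c0)] * (1 - fr) * (1 - fc) + M[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    M[cbind(r0, c0 + 1)] * (1 - fr) * fc + M[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Measure the lumen diameter along the centerline
#'
#' At each (uniformly resampled) centerline station the diameter is the
#' edge-to-edge extent along the local perpendicular.  Two measurement paths
#' exist:
#' \itemize{
#' \item mask-based (default when `frame` is `NULL`): rays are marched
#'   across the binary mask in quarter-pixel steps; accuracy ~1 px.
#' \item subpixel (when the normalised `frame` is supplied): the perpendicular
#'   intensity profile is interpolated to the point where the contrast depth
#'   falls to a fraction `q` of its local centerline value, and the measured
#'   half-width is corrected by `1/sqrt(1-q^2)` for the circular-chord
#'   geometry of a revolved lumen.  This reaches well below a pixel on clean
#'   frames and is what the pipeline uses.
#' }
#'
#' @param mask a [segment_lumen()] result or logical matrix
#' @param centerline an [extract_centerline()] result
#' @param mm_per_px pixel calibration (mm)
#' @param frame optional normalised intensity frame enabling the subpixel path
#' @param q depth fraction for the subpixel edge (0 < q < 1)
#' @param step_mm arclength resampling step (default half a pixel)
#' @param smooth moving-average window applied to the diameters
#' @return object of class `diameter_profile`: `s_mm`, `d_mm`, `mm_per_px`
#' @export
measure_diameters <- function(mask, centerline, mm_per_px, frame = NULL,
                              q = 0.5, step_mm = mm_per_px / 2, smooth = 5L) {
  m <- if (inherits(mask, "lumen_mask")) mask$mask else mask
  stopifnot(inherits(centerline, "centerline"))
  smax <- max(centerline$s_mm)
  sq <- seq(0, smax, by = step_mm)
  rs <- approx(centerline$s_mm, centerline$rc[, 1], xout = sq)$y
  cs <- approx(centerline$s_mm, centerline$rc[, 2], xout = sq)$y
  n <- length(sq)
  tr <- c(rs[2] - rs[1], (rs[3:n] - rs[1:(n - 2)]) / 2, rs[n] - rs[n - 1])
  tc <- c(cs[2] - cs[1], (cs[3:n] - cs[1:(n - 2)]) / 2, cs[n] - cs[n - 1])
  tl <- sqrt(tr^2 + tc^2); tl[tl == 0] <- 1
  nrm <- cbind(-tc / tl, tr / tl)             # unit normal in (row, col)
  step_px <- 0.25
  nr <- nrow(m); nc <- ncol(m)
  bg <- if (!is.null(frame)) median(frame[!m]) else NA_real_

  half_width <- function(i, sgn) {
    r0 <- rs[i]; c0 <- cs[i]
    kmax <- ceiling(max(nr, nc) / step_px)
    if (is.null(frame)) {
      last_in <- 0
      for (k in seq_len(kmax)) {
        r <- r0 + sgn * k * step_px * nrm[i, 1]
        c <- c0 + sgn * k * step_px * nrm[i, 2]
        if (r < 1 || r > nr || c < 1 || c > nc)
          stop("measure_diameters: perpendicular ray left the image before exiting the mask (mask touches the border)")
        if (!m[round(r), round(c)]) return((k - 0.5) * step_px)
        last_in <- k
      }
      stop("measure_diameters: ray failed to exit mask")
    }
    # subpixel: interpolated crossing of the relative-depth threshold
    ks <- 0:ceiling(6 / mm_per_px / step_px)   # search out to 6 mm
    r <- r0 + sgn * ks * step_px * nrm[i, 1]
    c <- c0 + sgn * ks * step_px * nrm[i, 2]
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    if (!all(ok)) { ks <- ks[ok]; r <- r[ok]; c <- c[ok] }
    depth <- bg - bilinear(frame, r, c)
    d0 <- max(depth[seq_len(min(5, length(depth)))])
    if (!is.finite(d0) || d0 <= 0) return(NA_real_)
    thr <- q * d0
    below <- which(depth < thr)
    below <- below[below > 1]
    if (length(below) == 0L)
      stop("measure_diameters: perpendicular ray left the image before exiting the mask (mask touches the border)")
    j <- below[1]
    fr <- (depth[j - 1] - thr) / (depth[j - 1] - depth[j])
    x_q <- (ks[j - 1] + fr * (ks[j] - ks[j - 1])) * step_px
    x_q / sqrt(1 - q^2)
  }

  d_px <- vapply(seq_len(n), function(i) {
    h1 <- half_width(i, +1); h2 <- half_width(i, -1)
    h1 + h2
  }, numeric(1))
  if (anyNA(d_px)) {
    d_px <- approx(sq[!is.na(d_px)], d_px[!is.na(d_px)], xout = sq,
                   rule = 2)$y
  }
  d_mm <- smooth_ma(d_px * mm_per_px, smooth)
  if (any(d_mm <= 0)) stop("measure_diameters: non-positive diameter measured")
  structure(list(s_mm = sq, d_mm = d_mm, mm_per_px = mm_per_px),
            class = "diameter_profile")
}

#' @export
print.diameter_profile <- function(x, ...) {
  cat(sprintf("diameter_profile: %d samples over %.2f mm, d in [%.3f, %.3f] mm\n",
              length(x$s_mm), max(x$s_mm), min(x$d_mm), max(x$d_mm)))
  invisible(x)
}

#' Write / read a diameter profile as CSV (`s_mm,d_mm`)
#' @param profile a `diameter_profile`
#' @param file path
#' @return `write_diameter_csv` returns `file` invisibly
#' @export
write_diameter_csv <- function(profile, file) {
  write.csv(data.frame(s_mm = profile$s_mm, d_mm = profile$d_mm),
            file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_diameter_csv
#' @export
read_diameter_csv <- function(file, mm_per_px = NA_real_) {
  df <- read.csv(file)
  structure(list(s_mm = df$s_mm, d_mm = df$d_mm, mm_per_px = mm_per_px),
            class = "diameter_profile")
}
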