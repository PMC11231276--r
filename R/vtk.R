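# Legacy-ASCII VTK writers (no installed R package writes VTK; the format is
# line-oriented text, written directly).

#' Write a revolved surface as VTK PolyData or STL
#'
#' @param surface a [revolve_surface()] result
#' @param file output path
#' @return `file`, invisibly
#' @export
write_vtk_polydata <- function(surface, file) {
  v <- surface$vertices; f <- surface$faces
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "revolved lumen surface", "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(v))), con)
  writeLines(sprintf("%.6g %.6g %.6g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(file)
}

#' @rdname write_vtk_polydata
#' @export
write_stl <- function(surface, file) {
  v <- surface$vertices; f <- surface$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("solid lumen", con)
  for (k in seq_len(nrow(f))) {
    writeLines(c(sprintf("facet normal %.6g %.6g %.6g", n[k, 1], n[k, 2], n[k, 3]),
                 "  outer loop",
                 sprintf("    vertex %.6g %.6g %.6g",
                         v[f[k, ], 1], v[f[k, ], 2], v[f[k, ], 3]),
                 "  endloop", "endfacet"), con)
  }
  writeLines("endsolid lumen", con)
  invisible(file)
}

#' Write the axisymmetric grid (with optional cell data) as a VTK
#' structured grid
#'
#' @param grid a [build_grid()] grid
#' @param file output path
#' @param cell_data named list of matrices (n_axial x n_radial)
#' @return `file`, invisibly
#' @export
write_vtk_structured <- function(grid, file, cell_data = list()) {
  Z <- grid$Z; R <- grid$R
  np <- length(Z)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "axisymmetric vessel grid (mm)", "ASCII",
               "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", nrow(Z), ncol(Z)),
               sprintf("POINTS %d float", np)), con)
  # VTK expects x fastest: loop j (radial) outer, i (axial) inner
  writeLines(sprintf("%.6g %.6g 0", as.vector(Z), as.vector(R)), con)
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", (nrow(Z) - 1L) * (ncol(Z) - 1L)), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.6g", as.vector(cell_data[[nm]])), con)
    }
  }
  invisible(file)
}

#' Read back a legacy-ASCII VTK structured grid written by
#' [write_vtk_structured()]
#'
#' Quality-control reader used to verify that exported files round-trip;
#' parses only the subset of the format this package writes.
#'
#' @param file path to a `.vtk` file
#' @return list with `Z`, `R` point matrices and `cell_data` (named list)
#' @export
read_vtk_structured <- function(file) {
  ln <- readLines(file)
  dims <- as.integer(strsplit(sub("DIMENSIONS ", "", ln[grep("^DIMENSIONS", ln)]), " ")[[1]])
  ip <- grep("^POINTS", ln)
  np <- as.integer(strsplit(ln[ip], " ")[[1]][2])
  pts <- do.call(rbind, lapply(ln[(ip + 1):(ip + np)], function(x)
    as.numeric(strsplit(x, " ")[[1]])))
  Z <- matrix(pts[, 1], dims[1], dims[2])
  R <- matrix(pts[, 2], dims[1], dims[2])
  cd <- list()
  isc <- grep("^SCALARS", ln)
  nc <- (dims[1] - 1L) * (dims[2] - 1L)
  for (k in isc) {
    nm <- strsplit(ln[k], " ")[[1]][2]
    vals <- as.numeric(ln[(k + 2):(k + 1 + nc)])
    cd[[nm]] <- matrix(vals, dims[1] - 1L, dims[2] - 1L)
  }
  list(Z = Z, R = R, cell_data = cd)
}

#' Export a transient solution as a VTK time series
#'
#' Writes `step_####.vtk` files (structured grid + pressure/velocity cell
#' data in mmHg and m/s) and a `series.csv` index.
#'
#' @param history a [solve_transient()] result
#' @param dir output directory
#' @param every write every n-th stored step
#' @return the directory, invisibly
#' @export
write_field_history_vtk <- function(history, dir, every = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ks <- seq(1L, dim(history$p)[3], by = every)
  files <- character(0)
  for (k in ks) {
    fn <- file.path(dir, sprintf("step_%04d.vtk", k))
    write_vtk_structured(history$grid, fn, list(
      pressure_mmHg = Pa_to_mmHg(history$p[, , k]),
      uz_m_s = history$uz[, , k],
      ur_m_s = history$ur[, , k]))
    files <- c(files, fn)
  }
  write.csv(data.frame(step = ks, t_s = history$t[history$stored_steps][ks],
                       file = basename(files)),
            file.path(dir, "series.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}
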