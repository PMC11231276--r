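#' Pipeline configuration
#'
#' Resolved configuration for [run_pipeline()].  Every run archives the
#' resolved configuration (JSON) and its content hash next to its outputs.
#'
#' @param beta degree of stenosis of the synthetic vessel (%)
#' @param seed RNG seed for all synthetic stages
#' @param method boundary-condition methodology (1-4, see [assemble_bc()])
#' @param patient index of the synthetic patient used by methods 1, 2 and 4
#' @param cine_dir read frames from this directory instead of synthesising
#' @param imaging [imaging_params()] for the synthetic cine
#' @param rheology [rheology_params()]
#' @param cfg [sim_config()]
#' @param grid_opts list passed to [build_grid()]
#' @param wire_offset virtual wire position distal to the throat (mm)
#' @param noise_sd cine noise level (grey levels)
#' @param write_vtk write VTK field output
#' @param include_holmes add the optional HOLMES column to wall metrics
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(beta = 32, seed = 1L, method = 3L, patient = 1L,
                            cine_dir = NULL, imaging = imaging_params(),
                            rheology = rheology_params(), cfg = sim_config(),
                            grid_opts = list(n_axial = 60L, n_radial_core = 5L),
                            wire_offset = 10, noise_sd = 0,
                            write_vtk = FALSE, include_holmes = FALSE) {
  if (!method %in% 1:4) stop("pipeline_config: method must be 1-4")
  structure(list(beta = beta, seed = as.integer(seed), method = as.integer(method),
                 patient = as.integer(patient), cine_dir = cine_dir,
                 imaging = imaging, rheology = rheology, cfg = cfg,
                 grid_opts = grid_opts, wire_offset = wire_offset,
                 noise_sd = noise_sd, write_vtk = write_vtk,
                 include_holmes = include_holmes),
            class = "pipeline_config")
}

#' Synthetic patient cohort with waves, flows and ground-truth Windkessel sets
#'
#' Builds `n` synthetic patients around the bundled reference parameter sets
#' ([cohort_reference()]): per patient an aortic-like inlet pressure wave
#' (means jittered a few percent around 75 mmHg), the implied coronary flow
#' wave, the reference WK3 parameters, and a distal pressure trace generated
#' from them (the ground truth that [wk3_fit()] recovers).
#'
#' @param seed RNG seed
#' @param n number of patients (up to 5)
#' @param T cardiac period (s)
#' @return list of patients, each with `inlet_wave`, `flow`, `wk_true`,
#'   `distal_trace`
#' @export
make_cohort <- function(seed = 1L, n = 5L, T = 0.8) {
  ref <- cohort_reference()
  n <- min(n, nrow(ref))
  with_seed(seed, lapply(seq_len(n), function(i) {
    jm <- 1 + rnorm(1, sd = 0.03)
    ja <- 1 + rnorm(1, sd = 0.08)
    wave <- make_pressure_wave(mean = 75 * jm, pulse_amplitude = 40 * ja, T = T)
    wk <- wk3_params(ref$R1[i], ref$R2[i], ref$C[i])
    qmean <- mean(wave$p) / (wk$R1 + wk$R2)
    Q <- make_flow_wave(mean = qmean, pulse_amplitude = 0.9 * qmean, T = T)
    list(patient = i, inlet_wave = wave, flow = Q, wk_true = wk,
         distal_trace = make_distal_trace(Q, wk))
  }))
}

resolve_bc <- function(config, cohort) {
  i <- config$patient
  pat <- cohort[[i]]
  switch(as.character(config$method),
    "1" = {
      R_tot <- pat$wk_true$R1 + pat$wk_true$R2
      assemble_bc(1L, mean(pat$inlet_wave$p), list(R = R_tot, p_ref = 0))
    },
    "2" = {
      fit <- wk3_fit(pat$distal_trace, pat$flow)
      assemble_bc(2L, pat$inlet_wave, fit$params)
    },
    "3" = {
      fits <- lapply(cohort, function(p) wk3_fit(p$distal_trace, p$flow)$params)
      avg_wk <- average_wk3(fits)
      avg_wave <- average_waves_fft(lapply(cohort, `[[`, "inlet_wave"))
      assemble_bc(3L, avg_wave, avg_wk)
    },
    "4" = assemble_bc(4L, pat$inlet_wave, pat$distal_trace))
}

#' Run the full virtual-FFR pipeline
#'
#' Executes cine synthesis (or reading) - normalisation - end-diastolic frame
#' selection - lumen segmentation - branch pruning - centerline extraction -
#' subpixel diameter measurement - stenosis quantification - grid generation -
#' boundary-condition assembly - flow solution - FFR and wall metrics, and
#' writes all reports (CSV, JSON, optional VTK) into `run_dir`.
#'
#' @param config a [pipeline_config()]
#' @param run_dir output directory
#' @return invisible list with all intermediate objects (`cine`, `profile`,
#'   `stenosis`, `grid`, `bc`, `solution`, `ffr`, `wall`, paths)
#' @export
run_pipeline <- function(config = pipeline_config(), run_dir = tempfile("vffr_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(run_dir, "log.txt")
  stage <- function(name, expr) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), name),
        file = logf, append = TRUE)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  cfg_json <- file.path(run_dir, "config.json")
  jsonlite::write_json(config_to_list(config), cfg_json,
                       auto_unbox = TRUE, digits = NA, null = "null")
  hash <- unname(tools::md5sum(cfg_json))
  cat(sprintf("config md5 %s\n", hash), file = logf, append = TRUE)

  cine <- stage("synthesise/read cine", {
    if (!is.null(config$cine_dir)) read_cine(config$cine_dir)
    else {
      img <- config$imaging
      img$noise_sd <- config$noise_sd
      render_cine(make_radius_profile(beta_target = config$beta),
                  img, seed = config$seed)
    }
  })
  profile <- stage("segmentation", {
    ncine <- normalize_cine(cine)
    ed <- select_end_diastolic_frame(ncine)
    frame <- get_frame(ncine, ed)
    mask <- segment_lumen(frame, frame_index = ed)
    mask <- prune_side_branches(mask)
    cl <- extract_centerline(mask, cine$imaging$mm_per_px)
    measure_diameters(mask, cl, cine$imaging$mm_per_px, frame = frame)
  })
  write_diameter_csv(profile, file.path(run_dir, "diameter_profile.csv"))
  stenosis <- stage("stenosis quantification", compute_beta_profile(profile))
  write_stenosis_csv(stenosis, file.path(run_dir, "stenosis_report.csv"))
  trend <- fit_diameter_trend(profile)
  grid <- stage("grid generation",
                do.call(build_grid, c(list(profile = profile), config$grid_opts)))
  cohort <- stage("cohort synthesis", make_cohort(config$seed))
  bc <- stage("boundary conditions", resolve_bc(config, cohort))
  solution <- stage("flow solution", {
    if (bc$method == 1L) solve_steady(grid, config$rheology, bc, config$cfg)
    else solve_transient(grid, config$rheology, bc, config$cfg)
  })
  ffr <- stage("FFR", {
    if (bc$method == 1L)
      compute_ffr_steady(solution, stenosis, config$wire_offset)
    else compute_ffr(solution, stenosis, config$wire_offset)
  })
  wall <- stage("wall metrics", {
    if (bc$method == 1L) NULL
    else wall_metrics(wall_shear(solution), include_holmes = config$include_holmes)
  })
  report <- data.frame(beta_pct = stenosis$beta_max,
                       d_min_mm = stenosis$d_min, D_ref_mm = stenosis$D_ref,
                       slope_mm_per_mm = trend[["slope"]],
                       Pa_mmHg = ffr$Pa, Pd_mmHg = ffr$Pd, ffr = ffr$ffr,
                       s_wire_mm = ffr$s_wire, method = bc$method,
                       config_md5 = hash)
  write.csv(report, file.path(run_dir, "ffr_report.csv"),
            row.names = FALSE, quote = FALSE)
  if (!is.null(wall))
    write.csv(wall, file.path(run_dir, "wall_metrics.csv"),
              row.names = FALSE, quote = FALSE)
  if (config$write_vtk) {
    write_vtk_polydata(revolve_surface(profile),
                       file.path(run_dir, "lumen_surface.vtk"))
    if (bc$method != 1L)
      write_field_history_vtk(solution, file.path(run_dir, "fields"),
                              every = max(1L, dim(solution$p)[3] %/% 8L))
  }
  invisible(list(cine = cine, profile = profile, stenosis = stenosis,
                 trend = trend, grid = grid, bc = bc, solution = solution,
                 ffr = ffr, wall = wall, report = report,
                 run_dir = run_dir, config_md5 = hash))
}

config_to_list <- function(config) {
  lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
}

cli_usage <- function() {
  paste(
    "usage: vffr <command> [options]",
    "commands:",
    "  synth       --beta B --seed S --out DIR        synthesise a cine + waves",
    "  segment     --in DIR --out CSV                 cine -> diameter profile",
    "  reconstruct --profile CSV --out DIR            beta report + surface/grid",
    "  fit-wk      --pressure CSV --flow CSV --out CSV  fit WK3 parameters",
    "  avg-bc      --params CSV --out CSV             average WK3 parameter rows",
    "  report      --params CSV --out CSV             averaged BCs error report",
    "  solve       --beta B --method {1,2,3,4} --seed S --out DIR  full pipeline",
    "  converge    --beta B --levels n1,n2,n3 --out CSV  grid sensitivity (steady)",
    "options: --verbose, --help", sep = "\n")
}

cli_args <- function(argv) {
  out <- list(); i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (key %in% c("verbose", "help")) { out[[key]] <- TRUE; i <- i + 1L }
    else {
      if (i == length(argv)) stop("missing value for --", key)
      out[[key]] <- argv[i + 1L]; i <- i + 2L
    }
  }
  out
}

#' Command-line entry point
#'
#' Thin argv-based front end over the pipeline functions (see
#' `inst/cli/vffr.R` for the Rscript wrapper).  Returns an exit code:
#' 0 on success, 2 on usage errors, 1 on stage failures.
#'
#' @param argv character vector of command-line arguments
#' @return integer exit code, invisibly
#' @export
cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  emit <- function(...) cat(..., "\n")
  if (length(argv) == 0L || argv[1] %in% c("--help", "help")) {
    emit(cli_usage()); return(invisible(if (length(argv)) 0L else 2L))
  }
  cmd <- argv[1]
  known <- c("synth", "segment", "reconstruct", "fit-wk", "avg-bc",
             "report", "solve", "converge")
  opts <- tryCatch(cli_args(argv[-1]), error = function(e) e)
  if (inherits(opts, "error") || !cmd %in% known) {
    emit(if (!cmd %in% known) paste0("unknown command: ", cmd)
         else conditionMessage(opts))
    emit(cli_usage())
    return(invisible(2L))
  }
  if (isTRUE(opts$help)) { emit(cli_usage()); return(invisible(0L)) }
  if (!is.null(opts$method) && !(opts$method %in% as.character(1:4))) {
    emit("--method must be 1, 2, 3 or 4")
    emit(cli_usage())
    return(invisible(2L))
  }
  code <- tryCatch({
    switch(cmd,
      synth = {
        out <- opts$out %||% "."
        seed <- as.integer(opts$seed %||% 1)
        beta <- as.numeric(opts$beta %||% 32)
        cine <- render_cine(make_radius_profile(beta_target = beta),
                            imaging_params(), seed = seed)
        write_cine(cine, out)
        pat <- make_cohort(seed, n = 1L)[[1]]
        write_wave_csv(pat$inlet_wave, file.path(out, "inlet_wave.csv"))
        write_wave_csv(pat$flow, file.path(out, "flow_wave.csv"))
        write_wave_csv(pat$distal_trace, file.path(out, "distal_trace.csv"))
        emit("wrote cine and waves to ", out); 0L
      },
      segment = {
        cine <- read_cine(opts$`in`)
        ncine <- normalize_cine(cine)
        frame <- get_frame(ncine)
        mask <- prune_side_branches(segment_lumen(frame))
        cl <- extract_centerline(mask, cine$imaging$mm_per_px)
        prof <- measure_diameters(mask, cl, cine$imaging$mm_per_px, frame = frame)
        write_diameter_csv(prof, opts$out %||% "diameter_profile.csv")
        emit("wrote ", opts$out %||% "diameter_profile.csv"); 0L
      },
      reconstruct = {
        prof <- read_diameter_csv(opts$profile)
        out <- opts$out %||% "."
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        sten <- compute_beta_profile(prof)
        write_stenosis_csv(sten, file.path(out, "stenosis_report.csv"))
        write_vtk_polydata(revolve_surface(prof), file.path(out, "lumen_surface.vtk"))
        write_vtk_structured(build_grid(prof), file.path(out, "grid.vtk"))
        emit(sprintf("beta_max = %.1f%% at s = %.2f mm", sten$beta_max, sten$s_min)); 0L
      },
      `fit-wk` = {
        p <- read_wave_csv(opts$pressure); q <- read_wave_csv(opts$flow)
        fit <- wk3_fit(p, q)
        df <- data.frame(R1 = fit$params$R1, R2 = fit$params$R2, C = fit$params$C,
                         sse = fit$sse, iterations = fit$iterations,
                         converged = fit$converged)
        write.csv(df, opts$out %||% "wk3_fit.csv", row.names = FALSE, quote = FALSE)
        emit(sprintf("R1 = %.5f, R2 = %.5f, C = %.6f (SSE %.3g)",
                     fit$params$R1, fit$params$R2, fit$params$C, fit$sse)); 0L
      },
      `avg-bc` = {
        df <- read.csv(opts$params)
        avg <- average_wk3(lapply(seq_len(nrow(df)), function(i)
          wk3_params(df$R1[i], df$R2[i], df$C[i])))
        write.csv(data.frame(R1 = avg$R1, R2 = avg$R2, C = avg$C),
                  opts$out %||% "wk3_average.csv", row.names = FALSE, quote = FALSE)
        emit(sprintf("average: R1 = %.7f, R2 = %.6f, C = %.6f",
                     avg$R1, avg$R2, avg$C)); 0L
      },
      report = {
        df <- read.csv(opts$params)
        avg <- average_wk3(lapply(seq_len(nrow(df)), function(i)
          wk3_params(df$R1[i], df$R2[i], df$C[i])))
        errs <- t(vapply(seq_len(nrow(df)), function(i)
          wk3_error_report(wk3_params(df$R1[i], df$R2[i], df$C[i]), avg),
          numeric(3)))
        out <- data.frame(patient = df$patient %||% seq_len(nrow(df)),
                          R1_avg = avg$R1, R2_avg = avg$R2, C_avg = avg$C,
                          R1_err_pct = errs[, 1], R2_err_pct = errs[, 2],
                          C_err_pct = errs[, 3])
        if (!is.null(df$ffr_invasive) && !is.null(df$ffr_virtual))
          out$ffr_err_pct <- ffr_error(df$ffr_invasive, df$ffr_virtual)
        write.csv(out, opts$out %||% "bc_report.csv", row.names = FALSE, quote = FALSE)
        emit(sprintf("averaged RCR: %.7f %.6f %.6f", avg$R1, avg$R2, avg$C)); 0L
      },
      solve = {
        method <- as.integer(opts$method %||% 3)
        cfgp <- pipeline_config(beta = as.numeric(opts$beta %||% 32),
                                seed = as.integer(opts$seed %||% 1),
                                method = method, write_vtk = TRUE)
        res <- run_pipeline(cfgp, opts$out %||% tempfile("vffr_run_"))
        emit(sprintf("FFR = %.4f (method %d), outputs in %s",
                     res$ffr$ffr, method, res$run_dir)); 0L
      },
      converge = {
        beta <- as.numeric(opts$beta %||% 32)
        lev <- as.integer(strsplit(opts$levels %||% "30,60,120", ",")[[1]])
        pr <- make_radius_profile(beta_target = beta)
        prof <- structure(list(s_mm = pr$s, d_mm = 2 * pr$r, mm_per_px = NA),
                          class = "diameter_profile")
        pat <- make_cohort(as.integer(opts$seed %||% 1), n = 1L)[[1]]
        bc <- assemble_bc(1L, mean(pat$inlet_wave$p),
                          list(R = pat$wk_true$R1 + pat$wk_true$R2, p_ref = 0))
        grids <- lapply(lev, function(nx)
          build_grid(prof, n_axial = nx, n_radial_core = max(4L, nx %/% 8L)))
        rep <- convergence_study(list(profile = prof, rheology = rheology_params(),
                                      bc = bc, cfg = sim_config(),
                                      stenosis = compute_beta_profile(prof)),
                                 grids)
        df <- data.frame(cells = rep$cells, ffr = rep$ffr,
                         diff_pct = c(NA, rep$diff_pct))
        write.csv(df, opts$out %||% "convergence.csv", row.names = FALSE, quote = FALSE)
        print(rep); 0L
      })
  }, error = function(e) {
    emit("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}
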