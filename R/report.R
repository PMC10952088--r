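# End-to-end orchestration: run the requested analysis stages on one
# trajectory from a declarative config (an R list or a YAML file) and
# collect every result, with its parameters, into a summary report.

#' Build an analysis configuration
#'
#' @param trajectory an [aq_trajectory()], or `NULL` if `trajectory_file` is
#'   given.
#' @param trajectory_file path to a trajectory file.
#' @param format `"xyz"` or `"cpmd"` (for `trajectory_file`).
#' @param box_edge,frame_spacing,element_order passed to the reader.
#' @param temperature temperature in K (used for finite-size correction and
#'   298 K rescaling).
#' @param viscosity shear viscosity in Pa s.
#' @param stages character vector among `"rdf"`, `"hbond"`, `"diffusion"`,
#'   `"acf"`, `"density"`.
#' @param rdf,hbond,diffusion,acf,density named lists of per-stage parameter
#'   overrides (see the stage functions for names).
#' @param backend energy backend for the density stage.
#' @param ref_table descriptor reference table (data frame) for 298 K
#'   rescaling of the first-shell descriptors.
#' @param output_dir directory for artifact files (`NULL` for none).
#' @param seed master seed recorded in the report and set before the run.
#' @return a named list of class `aq_config`.
#' @export
analysis_config <- function(trajectory = NULL, trajectory_file = NULL,
                            format = c("xyz", "cpmd"), box_edge = NULL,
                            frame_spacing = NA_real_, element_order = NULL,
                            temperature = NA_real_, viscosity = NA_real_,
                            stages = c("rdf", "hbond", "diffusion", "acf"),
                            rdf = list(), hbond = list(), diffusion = list(),
                            acf = list(), density = list(), backend = NULL,
                            ref_table = NULL, output_dir = NULL, seed = 1L) {
  format <- match.arg(format)
  known <- c("rdf", "hbond", "diffusion", "acf", "density")
  if (!all(stages %in% known))
    stop("unknown stages: ", paste(setdiff(stages, known), collapse = ", "))
  structure(list(trajectory = trajectory, trajectory_file = trajectory_file,
                 format = format, box_edge = box_edge,
                 frame_spacing = frame_spacing, element_order = element_order,
                 temperature = temperature, viscosity = viscosity,
                 stages = stages, rdf = rdf, hbond = hbond,
                 diffusion = diffusion, acf = acf, density = density,
                 backend = backend, ref_table = ref_table,
                 output_dir = output_dir, seed = seed),
            class = "aq_config")
}

#' Read an analysis configuration from YAML
#'
#' The YAML keys mirror the arguments of [analysis_config()] (energy
#' backends, being functions, can only be supplied from R).
#'
#' @param path YAML file path.
#' @return an `aq_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(analysis_config, y)
}

run_stage <- function(results, name, fun) {
  out <- tryCatch(list(ok = TRUE, value = fun(), error = NA_character_),
                  error = function(e)
                    list(ok = FALSE, value = NULL, error = conditionMessage(e)))
  results[[name]] <- out
  results
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order (trajectory input and
#' topology assignment first, then structure, hydrogen bonding, dynamics and
#' density as requested), records every stage result or failure, and writes
#' plain-text artifacts when an output directory is configured. The run is
#' deterministic given the config and its seed.
#'
#' @param config an [analysis_config()] (or a named list with the same
#'   fields, or a YAML path).
#' @return an object of class `aq_report`; `tidy()` gives the summary table,
#'   `report$results` holds the full stage objects, and failed stages carry
#'   their error message while the others proceed.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  if (!inherits(config, "aq_config")) config <- do.call(analysis_config, config)
  set.seed(config$seed)

  traj <- config$trajectory
  if (is.null(traj)) {
    if (is.null(config$trajectory_file))
      stop("config needs either `trajectory` or `trajectory_file`")
    traj <- switch(config$format,
      xyz = read_xyz_trajectory(config$trajectory_file, config$box_edge,
                                config$frame_spacing),
      cpmd = read_cpmd_trajectory(config$trajectory_file,
                                  config$element_order, config$box_edge,
                                  config$frame_spacing))
  }
  results <- list()
  topology <- tryCatch(assign_water_topology(get_frame(traj, 1L)),
                       error = function(e) e)
  if (inherits(topology, "error"))
    stop("topology assignment failed: ", conditionMessage(topology))

  if ("rdf" %in% config$stages) {
    results <- run_stage(results, "rdf", function() {
      p <- config$rdf
      rdf <- do.call(compute_rdf, c(list(traj = traj, pair = "OO",
                                         topology = topology), p))
      peaks <- find_first_extrema(rdf, temperature = config$temperature)
      n_r2g <- tryCatch(coordination_number(rdf, "r2g_min"),
                        error = function(e) NA_real_)
      n_g <- tryCatch(coordination_number(rdf, "g_min"),
                      error = function(e) NA_real_)
      rescaled <- NULL
      if (!is.null(config$ref_table) && is.finite(config$temperature)) {
        rescaled <- lapply(
          setNames(nm = intersect(c("r_max1", "g_max1", "r_min1", "g_min1"),
                                  names(config$ref_table))),
          function(dn) rescale_descriptor_to_298K(peaks[[dn]], dn,
                                                  config$temperature,
                                                  config$ref_table))
      }
      list(rdf = rdf, peaks = peaks, n_OO_r2g = n_r2g, n_OO_g = n_g,
           rescaled_298K = rescaled)
    })
  }
  if ("hbond" %in% config$stages) {
    results <- run_stage(results, "hbond", function() {
      p <- config$hbond
      hb <- do.call(hbond_stats, c(list(traj = traj, topology = topology),
                                   p[names(p) %in% c("criterion", "frames",
                                                     "method")]))
      ang <- do.call(angle_distribution,
                     c(list(traj = traj, topology = topology),
                       p[names(p) %in% c("cutoff_OO", "cutoff_HO",
                                         "bin_width", "frames")]))
      list(stats = hb, angles = ang)
    })
  }
  if ("diffusion" %in% config$stages) {
    results <- run_stage(results, "diffusion", function() {
      p <- config$diffusion
      unw <- unwrap_trajectory(traj)
      msd <- do.call(compute_msd,
                     c(list(traj = unw, topology = topology),
                       p[names(p) %in% c("atoms", "max_lag", "origin_stride",
                                         "method")]))
      fit <- fit_diffusion(msd, fit_window = p$fit_window,
                           temperature = config$temperature,
                           box_edge = traj$box,
                           viscosity = if (is.null(config$viscosity))
                             NA_real_ else config$viscosity)
      list(msd = msd, fit = fit)
    })
  }
  if ("acf" %in% config$stages) {
    results <- run_stage(results, "acf", function() {
      p <- config$acf
      axes <- if (is.null(p$axes)) c("OH", "dipole") else p$axes
      orders <- if (is.null(p$orders)) c(1L, 2L) else p$orders
      out <- list()
      for (ax in axes) for (nn in orders) {
        acf <- orientational_acf(traj, topology, axis = ax, order = nn,
                                 max_lag = p$max_lag)
        rel <- tryCatch(
          fit_relaxation_time(acf,
                              fit_start = if (is.null(p$fit_start)) 1.0
                                          else p$fit_start,
                              fit_end = p$fit_end),
          error = function(e) NULL)
        out[[paste0(ax, "_", nn)]] <- list(acf = acf, fit = rel)
      }
      out
    })
  }
  if ("density" %in% config$stages) {
    results <- run_stage(results, "density", function() {
      if (is.null(config$backend))
        stop("the density stage needs an energy `backend` in the config")
      do.call(equilibrium_density,
              c(list(traj = traj, topology = topology,
                     backend = config$backend), config$density))
    })
  }

  report <- structure(
    list(results = results, config = config, topology = topology,
         n_frames = n_frames(traj), n_mol = n_molecules(topology),
         box = traj$box, seed = config$seed,
         failed = names(results)[!vapply(results, `[[`, TRUE, "ok")]),
    class = "aq_report"
  )
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' Write report artifacts to a directory
#'
#' Curves are written as two-column plain text, counts as CSV, and the
#' summary as a tab-separated table; every number carries its unit in the
#' summary.
#'
#' @param report an `aq_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "aq_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res <- report$results
  two_col <- function(df, path, header) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", header), con)
    writeLines(sprintf("%14.6f %14.8f", df[[1]], df[[2]]), con)
  }
  if (!is.null(res$rdf) && res$rdf$ok)
    two_col(res$rdf$value$rdf$data, file.path(dir, "rdf_OO.dat"),
            "r (Angstrom)   g_OO(r)")
  if (!is.null(res$diffusion) && res$diffusion$ok)
    two_col(res$diffusion$value$msd$data[, c("time", "msd")],
            file.path(dir, "msd.dat"), "t (ps)   MSD (Angstrom^2)")
  if (!is.null(res$acf) && res$acf$ok) {
    for (nmx in names(res$acf$value))
      two_col(res$acf$value[[nmx]]$acf$data[, c("time", "C")],
              file.path(dir, paste0("acf_", nmx, ".dat")),
              paste0("t (ps)   C_", nmx))
  }
  if (!is.null(res$hbond) && res$hbond$ok) {
    write.csv(data.frame(frame = res$hbond$value$stats$frames,
                         res$hbond$value$stats$total),
              file.path(dir, "hbond_counts.csv"), row.names = FALSE)
    ang <- res$hbond$value$angles$data
    two_col(ang[, c("angle", "beta_density")],
            file.path(dir, "angle_beta.dat"),
            "beta (degrees)   P(beta) (1/degree)")
  }
  s <- tidy(report)
  write.table(s, file.path(dir, "summary.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @export
print.aq_report <- function(x, ...) {
  cat("<aq_report> ", x$n_frames, " frames, ", x$n_mol,
      " molecules, box ", format(x$box, digits = 6), " A (seed ", x$seed,
      ")\n", sep = "")
  s <- tidy(x)
  if (nrow(s) > 0) {
    cat("  stage results:\n")
    for (i in seq_len(nrow(s)))
      cat(sprintf("    %-28s %12.5g %s\n", s$quantity[i], s$value[i],
                  s$unit[i]))
  }
  if (length(x$failed) > 0)
    cat("  FAILED stages: ", paste(x$failed, collapse = ", "), "\n", sep = "")
  invisible(x)
}
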