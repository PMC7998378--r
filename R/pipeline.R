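#' Pipeline orchestration, configuration and CLI
#'
#' A single YAML configuration drives the whole pipeline: every stage keeps
#' its parameters in one section, each parameter defaulting to the assay's
#' stated value where one exists (10 um zones/bins, 1.5 um band, 50/100 um
#' rolling ball, 0.225 normalized-green and 0.55 ratio thresholds, 24 h
#' non-cycling rule). All randomness flows from a single seed through one
#' derivation scheme, so a run repeated with the same config is
#' byte-identical.
#'
#' @name pipeline_cli
NULL

#' Default run configuration
#'
#' @param seed Master seed.
#' @param stages Character vector of stages to run; subset of
#'   `cfa`, `foci`, `fucci`, `cdk2`, `section`, `spheroid3d`.
#' @return Nested list of class `run_config` with per-stage sections.
#' @export
default_run_config <- function(seed = 1L,
                               stages = c("cfa", "foci", "fucci", "cdk2",
                                          "section", "spheroid3d")) {
  cfg <- list(
    seed = as.integer(seed),
    stages = stages,
    calibration = list(pixel_size_um = 0.65, frame_interval_h = 0.5,
                       z_step_um = 10),
    cfa = list(alpha = 0.2, beta = 0.02, doses = c(0, 2, 4, 6, 8),
               seeded_per_well = 250, plating_efficiency = 0.5,
               replicates = 6),
    foci = list(n_nuclei = 70, foci_mean = 10, tophat_radius_um = 1.5,
                focus_diameter_um = 2, k_mad = 5, min_area_um2 = 30),
    fucci = list(n_cells = 200, phase_means_h = c(earlyG1 = 2, G1 = 8,
                                                  S = 7, G2 = 3),
                 noncycling_fraction = 0.3, noncycling_hours = 24,
                 movie_h = 120, movie_end_rule = "threshold"),
    cdk2 = list(n_cells = 100, ratio = 0.8, band_width_um = 1.5,
                rollball_radius_um = 50, quiescence_threshold = 0.55),
    section = list(radius_um = 250, hypoxia_onset_um = 100,
                   proliferation_depth_um = 80, zone_width_um = 10,
                   pixel_size_um = 1.3),
    spheroid3d = list(radius_um = 200, green_rim_depth_um = 50,
                      rollball_um = 100, bin_um = 10,
                      green_threshold = 0.225, pixel_size_um = 1.3)
  )
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its default. The effective config round-trips: serialize and re-parse
#' give identical effective parameters.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config(seed = user$seed %||% 1L)
  merge_in <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_in(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  structure(merge_in(unclass(cfg), user), class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run configuration to YAML
#' @param config A `run_config`.
#' @param path Output file.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
}

validate_run_config <- function(config) {
  errs <- character(0)
  known <- c("cfa", "foci", "fucci", "cdk2", "section", "spheroid3d")
  bad <- setdiff(config$stages, known)
  if (length(bad))
    errs <- c(errs, sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  if (!is.numeric(config$seed)) errs <- c(errs, "seed: must be numeric")
  for (f in c("pixel_size_um", "frame_interval_h", "z_step_um"))
    if (!is.numeric(config$calibration[[f]]) || config$calibration[[f]] <= 0)
      errs <- c(errs, sprintf("calibration.%s: must be a positive number", f))
  for (stage in intersect(config$stages, known)) {
    sec <- config[[stage]]
    inp <- sec$input
    if (!is.null(inp) && !file.exists(inp))
      errs <- c(errs, sprintf("%s.input: file not found: %s", stage, inp))
  }
  if (length(errs)) stop("invalid configuration:\n  ",
                         paste(errs, collapse = "\n  "), call. = FALSE)
  invisible(TRUE)
}

write_table <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the pipeline
#'
#' Executes the requested stages in order. Stages with an `input` path read
#' it (CSV); otherwise the stage generates its input synthetically from the
#' config seed, analyzes it, and writes its tables to `out_dir`. A JSON run
#' report (parameter echo, per-stage outputs and timing, warnings) is
#' written alongside.
#'
#' @param config A `run_config` (or path to a YAML file).
#' @param out_dir Output directory (created if needed).
#' @return The run report, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cal <- config$calibration
  report <- list(package_version = as.character(utils::packageVersion("hypoxiq")),
                 seed = config$seed, config = unclass(config),
                 stages = list())
  warn <- character(0)
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- withCallingHandlers(fun(), warning = function(w) {
      warn <<- c(warn, sprintf("%s: %s", name, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    list(outputs = out, seconds = round(proc.time()[["elapsed"]] - t0, 3))
  }
  scfg <- function(px) sim_config(seed = config$seed, pixel_size_um = px,
                                  frame_interval_h = cal$frame_interval_h)
  for (stage in config$stages) {
    report$stages[[stage]] <- switch(stage,
      cfa = run_stage("cfa", function() {
        p <- config$cfa
        plate <- if (!is.null(p$input)) read.csv(p$input) else
          simulate_cfa_counts(p$alpha, p$beta, p$doses, p$seeded_per_well,
                              p$plating_efficiency, p$replicates,
                              scfg(cal$pixel_size_um))
        sf <- surviving_fractions(plate)
        fit <- fit_lq(sf)
        fit_tab <- data.frame(alpha = fit$alpha, beta = fit$beta,
                              rss = fit$rss, df = fit$df,
                              d10_gy = dose_for_sf(fit, 0.1))
        c(write_table(plate, out_dir, "cfa_plate.csv"),
          write_table(sf, out_dir, "cfa_survival.csv"),
          write_table(fit_tab, out_dir, "cfa_fit.csv"))
      }),
      foci = run_stage("foci", function() {
        p <- config$foci
        img <- generate_foci_image(p$n_nuclei, p$foci_mean,
                                   scfg(cal$pixel_size_um))
        labels <- segment_nuclei(img$channels$dapi, img$pixel_size_um,
                                 min_area_um2 = p$min_area_um2)
        tab <- count_foci(img$channels$foci, labels, img$pixel_size_um,
                          p$tophat_radius_um, p$focus_diameter_um, p$k_mad)
        write_table(tab, out_dir, "foci_counts.csv")
      }),
      fucci = run_stage("fucci", function() {
        p <- config$fucci
        traces <- if (!is.null(p$input)) read.csv(p$input) else
          generate_fucci_traces(p$n_cells, unlist(p$phase_means_h),
                                p$noncycling_fraction,
                                scfg(cal$pixel_size_um),
                                movie_h = p$movie_h)
        dur <- trace_durations_table(traces,
                                     noncycling_hours = p$noncycling_hours,
                                     movie_end_rule = p$movie_end_rule)
        c(write_table(traces, out_dir, "fucci_traces.csv"),
          write_table(dur, out_dir, "fucci_durations.csv"))
      }),
      cdk2 = run_stage("cdk2", function() {
        p <- config$cdk2
        img <- generate_reporter_image(p$ratio, p$n_cells,
                                       scfg(cal$pixel_size_um))
        meas <- cdk2_pipeline(img$channels$reporter, img$channels$nuclei,
                              img$pixel_size_um,
                              reporter_params(p$band_width_um,
                                              p$rollball_radius_um,
                                              p$quiescence_threshold))
        s <- attr(meas, "summary")
        c(write_table(meas, out_dir, "cdk2_ratios.csv"),
          write_table(data.frame(fraction = s$fraction,
                                 n_quiescent = s$n_quiescent,
                                 n_total = s$n_total),
                      out_dir, "cdk2_summary.csv"))
      }),
      section = run_stage("section", function() {
        p <- config$section
        gen <- generate_section_image(p$radius_um, p$hypoxia_onset_um,
                                      p$proliferation_depth_um,
                                      scfg(p$pixel_size_um))
        prof <- section_pipeline(gen$pimo, gen$brdu, p$pixel_size_um,
                                 p$zone_width_um)
        write_table(prof, out_dir, "section_zones.csv")
      }),
      spheroid3d = run_stage("spheroid3d", function() {
        p <- config$spheroid3d
        st <- generate_spheroid_stack(p$radius_um, p$green_rim_depth_um,
                                      cal$z_step_um, scfg(p$pixel_size_um))
        res <- spheroid3d_pipeline(st, p$rollball_um, p$bin_um,
                                   p$green_threshold)
        c(write_table(res$cells, out_dir, "spheroid_cells.csv"),
          write_table(res$histogram, out_dir, "spheroid_histogram.csv"))
      }),
      stop("unknown stage: ", stage))
  }
  report$warnings <- warn
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Command-line entry point
#'
#' Verbs: `run --config cfg.yaml --out DIR [--seed N]`;
#' `simulate <cfa|foci|fucci|cdk2|section|spheroid3d> --out DIR [--seed N]`;
#' `cfa fit --in plate.csv --out DIR`;
#' `fucci trace --in traces.csv --out DIR`.
#' An installed wrapper script lives at `inst/cli/hypoxiq`.
#'
#' @param args Character vector (default `commandArgs(trailingOnly=TRUE)`).
#' @return Exit status, invisibly.
#' @export
hypoxiq_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  getopt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  if (length(args) == 0) {
    cat("usage: hypoxiq <run|simulate|cfa|fucci> ...\n")
    return(invisible(1L))
  }
  verb <- args[1]
  out <- getopt("--out", "hypoxiq_out")
  seed <- as.integer(getopt("--seed", "1"))
  if (verb == "run") {
    cfgp <- getopt("--config")
    config <- if (is.null(cfgp)) default_run_config(seed) else
      read_run_config(cfgp)
    if (!is.null(getopt("--seed"))) config$seed <- seed
    run_pipeline(config, out)
  } else if (verb == "simulate") {
    kind <- args[2]
    config <- default_run_config(seed, stages = kind)
    run_pipeline(config, out)
  } else if (verb == "cfa" && args[2] == "fit") {
    config <- default_run_config(seed, stages = "cfa")
    config$cfa$input <- getopt("--in")
    run_pipeline(config, out)
  } else if (verb == "fucci" && args[2] == "trace") {
    config <- default_run_config(seed, stages = "fucci")
    config$fucci$input <- getopt("--in")
    run_pipeline(config, out)
  } else {
    cat("unknown verb: ", verb, "\n")
    return(invisible(1L))
  }
  invisible(0L)
}
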