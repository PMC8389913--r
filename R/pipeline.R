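#' Run the full surface-construction and adsorption-analysis pipeline
#'
#' Executes, in dependency order, the stages configured in a YAML file or
#' list: `build` (slab or nanoparticle), `hydroxylate`, optionally
#' `compose`, `synth` (synthetic trajectory), `profile`, and `bind`.  All
#' stage parameters are validated before any stage runs; every output is
#' stamped with the global seed and the configuration it came from, and the
#' run is fully deterministic for a fixed configuration.
#'
#' @param config Path to a YAML configuration, or an equivalent named list.
#'   Recognized blocks and defaults:
#' \preformatted{
#' seed: 1
#' outdir: "titania-out"
#' build:       {kind: slab, phase: anatase, miller: "101",
#'               n_u: 4, n_v: 2, n_layers: 2}       # or kind: nanoparticle, radius: ...
#' hydroxylate: {fraction: 0.30, q_oh: -0.40}
#' synth:       {n_lipids: 80, frame_interval: 5, duration: 1000}
#' profile:     {bin_width: 0.01, normalization: volumetric, stride: 1}
#' bind:        {layer_width: 1.0, smoothing: 3, min_prominence: 0.02,
#'               gap_tolerance_frames: 0}
#' }
#' @param outdir Output directory override.
#' @return A `pipeline_report` list: paths of written artifacts, per-stage
#'   timings and record counts, the effective configuration, and the
#'   fitted `binding_fit`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stopifnot(is.list(cfg))
  cfg <- validate_pipeline_config(cfg)
  outdir <- outdir %||% cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = cfg, seed = cfg$seed, stages = list(),
                 artifacts = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    report$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    val
  }

  model <- t_stage("build", {
    b <- cfg$build
    if (b$kind == "slab") {
      build_slab(b$phase, b$miller, b$n_u, b$n_v, b$n_layers)
    } else {
      carve_nanoparticle(b$phase, b$radius)
    }
  })
  report$stages$build$n_atoms <- nrow(model$atoms)

  hyd <- cfg$hydroxylate
  census <- compute_coordination(model)
  area_nm2 <- if (inherits(model, "tio2_slab")) 2 * model$face_area / 100 else
    4 * pi * (model$radius / 10)^2
  plan <- t_stage("hydroxylate", {
    plan_hydroxylation(census, fraction = hyd$fraction, seed = cfg$seed,
                       q_oh = hyd$q_oh, exposed_area_nm2 = area_nm2)
  })
  model <- attach_hydroxyls(model, plan)
  report$stages$hydroxylate$n_oh <- plan$n_oh
  report$stages$hydroxylate$sigma <- plan$sigma

  structure_path <- file.path(outdir, "structure.gro")
  write_gro(model, path = structure_path)
  plan_path <- file.path(outdir, "hydroxylation.json")
  write_plan(plan, plan_path)

  if (!is.null(cfg$compose)) {
    cmp <- cfg$compose
    nlip <- cmp$n_lipids %||%
      lipid_count(model$face_area / 100, composition_rule())
    comp <- system_composition(cmp$lipid %||% "POPE", nlip,
                               cmp$n_cholesterol %||% 0L)
    system <- t_stage("compose", {
      assemble_initial_state(model, comp, seed = cfg$seed)
    })
    write_gro(system, path = file.path(outdir, "system.gro"))
    report$stages$compose$n_water <- system$composition$n_water
    report$artifacts$system <- file.path(outdir, "system.gro")
  }

  sy <- cfg$synth
  series <- t_stage("synth", {
    generate_distance_series(traj_spec(
      n_lipids = sy$n_lipids, frame_interval = sy$frame_interval,
      duration = sy$duration, seed = cfg$seed))
  })
  report$stages$synth$n_frames <- n_frames(series)
  series_path <- file.path(outdir, "distances.tsv")
  write_distance_series(series, series_path)

  pr <- cfg$profile
  prof <- t_stage("profile", {
    closest_atom_profile(series, bin_width = pr$bin_width,
                         normalization = pr$normalization,
                         geometry = list(type = "slab",
                                         face_area_nm2 = model$face_area / 100),
                         stride = pr$stride)
  })
  profile_path <- file.path(outdir, "profile.tsv")
  utils::write.table(data.frame(r_nm = prof$r, value = prof$value),
                     profile_path, sep = "\t", row.names = FALSE, quote = FALSE)

  bd <- cfg$bind
  fit <- t_stage("bind", {
    binding_analysis(series, bin_width = pr$bin_width,
                     layer_width = bd$layer_width, smoothing = bd$smoothing,
                     min_prominence = bd$min_prominence,
                     gap_tolerance_frames = bd$gap_tolerance_frames)
  })
  modes_path <- file.path(outdir, "binding_modes.tsv")
  utils::write.table(binding_mode_table(fit, surface_label(cfg$build)),
                     modes_path, sep = "\t", row.names = FALSE, quote = FALSE)
  ads_path <- file.path(outdir, "adsorption.tsv")
  utils::write.table(adsorption_table(fit, surface_label(cfg$build)),
                     ads_path, sep = "\t", row.names = FALSE, quote = FALSE)

  report$artifacts <- c(report$artifacts,
                        list(structure = structure_path, plan = plan_path,
                             distances = series_path, profile = profile_path,
                             binding_modes = modes_path, adsorption = ads_path))
  report$fit <- fit
  report_path <- file.path(outdir, "report.json")
  jsonlite::write_json(
    list(seed = cfg$seed, config = cfg,
         stages = report$stages,
         artifacts = lapply(report$artifacts, basename)),
    report_path, auto_unbox = TRUE, digits = NA)
  report$artifacts$report <- report_path
  class(report) <- "pipeline_report"
  report
}

surface_label <- function(build) {
  if (build$kind == "slab") {
    sprintf("%s(%s)", build$phase, paste(parse_miller(build$miller), collapse = ""))
  } else sprintf("%s NP R=%g A", build$phase, build$radius)
}

# fill defaults and validate every stage block before anything runs
validate_pipeline_config <- function(cfg) {
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$outdir <- cfg$outdir %||% "titania-out"
  for (blk in c("build", "synth", "profile", "bind")) {
    if (is.null(cfg[[blk]])) {
      stop(sprintf("pipeline configuration is missing the required '%s' block", blk),
           call. = FALSE)
    }
  }
  b <- cfg$build
  b$kind <- b$kind %||% "slab"
  if (!b$kind %in% c("slab", "nanoparticle")) {
    stop("build$kind must be 'slab' or 'nanoparticle'", call. = FALSE)
  }
  if (is.null(b$phase) || !b$phase %in% c("anatase", "rutile")) {
    stop("build$phase must be 'anatase' or 'rutile'", call. = FALSE)
  }
  if (b$kind == "slab") {
    if (is.null(b$miller)) stop("build$miller is required for slabs", call. = FALSE)
    face_basis(b$phase, parse_miller(b$miller))
    b$n_u <- b$n_u %||% 4L; b$n_v <- b$n_v %||% 2L; b$n_layers <- b$n_layers %||% 2L
    if (b$n_layers < 2) stop("build$n_layers must be >= 2", call. = FALSE)
  } else {
    if (is.null(b$radius) || b$radius < 8) {
      stop("build$radius must be >= 8 angstrom", call. = FALSE)
    }
  }
  cfg$build <- b
  h <- cfg$hydroxylate %||% list()
  h$fraction <- h$fraction %||% 0.30
  if (h$fraction < 0 || h$fraction > 1) {
    stop("hydroxylate$fraction must be in [0, 1]", call. = FALSE)
  }
  h$q_oh <- h$q_oh %||% -0.40
  cfg$hydroxylate <- h
  s <- cfg$synth
  s$n_lipids <- s$n_lipids %||% 80L
  s$frame_interval <- s$frame_interval %||% 5
  s$duration <- s$duration %||% 1000
  if (s$duration < 10 * s$frame_interval / 1000) {
    stop("synth$duration must cover at least 10 frames", call. = FALSE)
  }
  cfg$synth <- s
  p <- cfg$profile
  p$bin_width <- p$bin_width %||% 0.01
  if (p$bin_width <= 0) stop("profile$bin_width must be > 0", call. = FALSE)
  p$normalization <- p$normalization %||% "volumetric"
  if (!p$normalization %in% c("volumetric", "per_frame")) {
    stop("profile$normalization must be 'volumetric' or 'per_frame'", call. = FALSE)
  }
  p$stride <- p$stride %||% 1L
  cfg$profile <- p
  bd <- cfg$bind
  bd$layer_width <- bd$layer_width %||% 1.0
  if (bd$layer_width < 0) stop("bind$layer_width must be >= 0", call. = FALSE)
  bd$smoothing <- bd$smoothing %||% 3L
  bd$min_prominence <- bd$min_prominence %||% 0.02
  bd$gap_tolerance_frames <- bd$gap_tolerance_frames %||% 0L
  cfg$bind <- bd
  cfg
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline run (seed %d): %d stages\n", x$seed, length(x$stages)))
  for (nm in names(x$stages)) {
    cat(sprintf("  %-12s %6.2f s\n", nm, x$stages[[nm]]$seconds))
  }
  cat("artifacts:", paste(basename(unlist(x$artifacts)), collapse = ", "), "\n")
  invisible(x)
}
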