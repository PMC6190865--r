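#' Assemble and validate a pipeline run configuration
#'
#' A single configuration drives the whole synthetic pipeline
#' (simulate -> build images -> evidence -> group RFX -> maps), replacing
#' stateful multi-script workflows. Any field can be overridden; unknown
#' fields are rejected. `models` is a named list mapping model names to
#' condition -> weight mappings.
#'
#' @param ... Named overrides of the defaults (see Details), or a single
#'   list, or a path to a YAML/JSON file with the same fields.
#' @return A validated list of class `bms_run_config`.
#' @details Fields and defaults:
#' `n_subjects` (21), `n_trials_per_condition` (30), `conditions`
#' (UP/AP/UU/AU), `models` (Opposition `[1,2,2,3]`, Interaction `[1,4,2,3]`),
#' `assignments` (NULL: random), `effect_size` (1), `noise_sd` (1),
#' `intercept` (0), `grid_size` (32x32), `n_time` (80), `effect_time`
#' (31..40), `coeff_precision` (1e-3), `noise_shape`/`noise_rate` (1e-3),
#' `vb_tol` (1e-4), `vb_max_iter` (128), `smooth_fwhm` (1 voxel),
#' `alpha0` (1), `rfx_tol` (1e-6), `mc_samples` (1e6), `threshold` (0.75),
#' `min_cluster` (0), `connectivity` (6), `seed` (1), `out_dir` ("bms_run").
#' @export
run_config <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args))) {
    if (is.character(args[[1]])) {
      path <- args[[1]]
      if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
      args <- if (grepl("\\.json$", path)) {
        jsonlite::read_json(path, simplifyVector = TRUE)
      } else {
        yaml::read_yaml(path)
      }
    } else if (is.list(args[[1]])) {
      args <- args[[1]]
    }
  }
  defaults <- list(
    n_subjects = 21, n_trials_per_condition = 30,
    conditions = c("UP", "AP", "UU", "AU"),
    models = list(Opposition = c(UP = 1, AP = 2, UU = 2, AU = 3),
                  Interaction = c(UP = 1, AP = 4, UU = 2, AU = 3)),
    assignments = NULL, effect_size = 1, noise_sd = 1, intercept = 0,
    grid_size = c(32, 32), n_time = 80, effect_time = 31:40,
    coeff_precision = 1e-3, noise_shape = 1e-3, noise_rate = 1e-3,
    vb_tol = 1e-4, vb_max_iter = 128, smooth_fwhm = 1,
    alpha0 = 1, rfx_tol = 1e-6, mc_samples = 1e6,
    threshold = 0.75, min_cluster = 0, connectivity = 6,
    seed = 1, out_dir = "bms_run")
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- modifyList(defaults, args, keep.null = TRUE)
  if (length(cfg$conditions) < 2L) stop("config: need >= 2 conditions.", call. = FALSE)
  if (length(cfg$models) < 1L) stop("config: need >= 1 model.", call. = FALSE)
  for (nm in names(cfg$models)) {
    w <- unlist(cfg$models[[nm]])
    if (!all(cfg$conditions %in% names(w))) {
      stop("config: model '", nm, "' does not map every condition.", call. = FALSE)
    }
  }
  if (cfg$threshold < 0 || cfg$threshold > 1) {
    stop("config: `threshold` must be in [0, 1].", call. = FALSE)
  }
  structure(cfg, class = "bms_run_config")
}

config_specs <- function(cfg) {
  lapply(names(cfg$models), function(nm) model_spec(nm, unlist(cfg$models[[nm]])))
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  flat <- unclass(cfg)
  flat$out_dir <- NULL
  jsonlite::write_json(flat[order(names(flat))], f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Run the full synthetic BMS mapping pipeline
#'
#' Executes simulate -> scalp-time images -> per-voxel VB evidence ->
#' voxel-wise RFX -> thresholded maps, writing every stage's outputs and a
#' machine-readable manifest (config hash, seeds, per-stage files and
#' checksums) under `config$out_dir`. The expensive evidence stage is
#' skipped and reloaded from disk when a previous run with an identical
#' configuration hash left complete outputs; a stage failure aborts with the
#' failing stage named, retaining partial outputs.
#'
#' @param config A [run_config()] (or anything accepted by it).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the run directory, the `bms_result`, the
#'   `bms_report` and the simulation ground truth.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  cfg <- if (inherits(config, "bms_run_config")) config else run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  prev <- if (file.exists(manifest_path)) {
    tryCatch(jsonlite::read_json(manifest_path, simplifyVector = TRUE),
             error = function(e) NULL)
  }
  manifest <- list(config = unclass(cfg), config_hash = hash,
                   package_version = as.character(utils::packageVersion("bmsmaps")),
                   r_version = R.version.string, stages = list())
  say <- function(...) if (!quiet) message(...)
  run_stage <- function(name, expr) {
    say("[", name, "] ...")
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    res
  }
  record <- function(name, dir) {
    files <- list.files(dir, recursive = TRUE, full.names = TRUE)
    manifest$stages[[name]] <<- list(
      dir = dir, config_hash = hash,
      files = as.list(setNames(unname(tools::md5sum(files)), basename(files))))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  }

  specs <- config_specs(cfg)

  sim <- run_stage("simulate", {
    s <- simulate_group(n_subjects = cfg$n_subjects,
                        n_trials_per_condition = cfg$n_trials_per_condition,
                        conditions = cfg$conditions, model_specs = specs,
                        assignments = cfg$assignments,
                        effect_size = cfg$effect_size, noise_sd = cfg$noise_sd,
                        intercept = cfg$intercept, grid_size = cfg$grid_size,
                        n_time = cfg$n_time, effect_time = cfg$effect_time,
                        seed = cfg$seed)
    write_simulation(s, file.path(cfg$out_dir, "simulation"))
    s
  })
  record("simulate", file.path(cfg$out_dir, "simulation"))

  ev_dir <- file.path(cfg$out_dir, "evidence")
  reuse <- !is.null(prev) && identical(prev$stages$evidence$config_hash, hash) &&
    file.exists(file.path(ev_dir, "evidence_meta.json"))
  maps <- if (reuse) {
    say("[evidence] unchanged config; reloading from ", ev_dir)
    read_evidence_maps(ev_dir)
  } else {
    run_stage("evidence", {
      priors <- vb_priors(cfg$coeff_precision, cfg$noise_shape, cfg$noise_rate)
      images <- lapply(sim$datasets, build_scalp_time_volumes,
                       grid_size = cfg$grid_size)
      m <- evidence_maps(images, specs, priors = priors, tol = cfg$vb_tol,
                         max_iter = cfg$vb_max_iter, smooth_fwhm = cfg$smooth_fwhm)
      write_evidence_maps(m, ev_dir)
      m
    })
  }
  record("evidence", ev_dir)

  result <- run_stage("rfx", {
    r <- voxelwise_bms(maps, alpha0 = cfg$alpha0, tol = cfg$rfx_tol,
                       n_samples = cfg$mc_samples, seed = cfg$seed)
    write_bms_result(r, file.path(cfg$out_dir, "bms"))
    r
  })
  record("rfx", file.path(cfg$out_dir, "bms"))

  report <- run_stage("map", {
    bms_report(result, threshold = cfg$threshold, min_size = cfg$min_cluster,
               connectivity = cfg$connectivity,
               out_dir = file.path(cfg$out_dir, "maps"))
  })
  record("map", file.path(cfg$out_dir, "maps"))

  say("pipeline complete: ", cfg$out_dir)
  invisible(list(out_dir = cfg$out_dir, result = result, report = report,
                 truth = sim$truth, maps = maps))
}
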