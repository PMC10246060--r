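# Unified command-line surface: config handling and subcommand dispatch.
# The exec/tmsfield script is a thin wrapper around tmsMain().

#' Default run configuration
#'
#' All tunables of the pipeline with their defaults; every source of
#' randomness has an explicit seed. Serialized as YAML for the CLI.
#'
#' @return nested named list.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    head = list(outer_radius_mm = 55, grid_shape = c(48L, 48L, 48L),
                voxel_mm = 2.5, anisotropy_ratio = 3, anisotropy_seed = 1L),
    coil = list(loop_radius_mm = 27, loop_center_offset_mm = 27,
                segments_per_loop = 64L, didt = 1e6),
    placements = list(n_cases = 300L, n_directions = 78L, standoff_mm = 2,
                      seed = 1L),
    solver = list(tol = 1e-8),
    fov_shape = c(24L, 24L, 24L),
    train = list(levels = 3L, base_channels = 4L, epochs = 100L,
                 batch_size = 4L, lr = 3e-3, seed = 1L),
    serve = list(n_runs = 50L),
    streamlines = list(n = 25L, points_per_line = 20L, seed = 1L))
}

#' Read a YAML run configuration
#'
#' Values are merged over [defaultRunConfig()]; unknown keys (at top level or
#' within sections) are rejected.
#'
#' @param path YAML file path, or NULL for the defaults.
#' @return nested named list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_into <- function(base, new, where) {
    for (k in names(new)) {
      if (!k %in% names(base))
        stop(sprintf("unknown config key '%s%s'", where, k))
      if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
        base[[k]] <- merge_into(base[[k]], new[[k]], paste0(where, k, "."))
      } else {
        base[[k]] <- new[[k]]
      }
    }
    base
  }
  merge_into(cfg, user, "")
}

.cli_log <- function(...) message(sprintf(...))

.parse_argv <- function(argv) {
  flags <- list()
  pos <- character(0)
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(argv) || startsWith(argv[i + 1L], "--")) {
        flags[[key]] <- TRUE
        i <- i + 1L
      } else {
        flags[[key]] <- argv[i + 1L]
        i <- i + 2L
      }
    } else {
      pos <- c(pos, a)
      i <- i + 1L
    }
  }
  list(pos = pos, flags = flags)
}

.cli_head <- function(cfg) {
  hd <- makeSphereHead(outer_radius_mm = cfg$head$outer_radius_mm,
                       grid_shape = cfg$head$grid_shape,
                       voxel_mm = cfg$head$voxel_mm)
  wm_outer <- min(hd$geometry@shell_radii)
  cv <- randomizeConductivityTensors(
    hd$conductivity, center = hd$geometry@center,
    wm_shell = c(0, wm_outer), anisotropy_ratio = cfg$head$anisotropy_ratio,
    seed = cfg$head$anisotropy_seed)
  list(conductivity = cv, geometry = hd$geometry)
}

.cli_coil <- function(cfg) {
  makeFigure8Coil(cfg$coil$loop_radius_mm, cfg$coil$loop_center_offset_mm,
                  cfg$coil$segments_per_loop, cfg$coil$didt)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `make-head`, `sample-placements`, `dadt`,
#' `solve`, `make-dataset`, `train`, `predict`, `evaluate`, `serve`,
#' `client-demo`, `benchmark`, `reproduce-table2` and `demo`. Common flags: `--config`
#' (YAML), `--seed`, `--out` (artifact directory). Returns the process exit
#' code (0 on success); logs go to stderr, artifacts to the output directory.
#'
#' @param argv character vector of command-line arguments (without the
#'   program name).
#' @return integer exit code.
#' @export
tmsMain <- function(argv = commandArgs(trailingOnly = TRUE)) {
  parsed <- .parse_argv(argv)
  if (isTRUE(parsed$flags$version) || (length(parsed$pos) && parsed$pos[1] == "version")) {
    cat(sprintf("tmsfield %s\n", as.character(utils::packageVersion("tmsfield"))))
    return(0L)
  }
  if (!length(parsed$pos)) {
    message("usage: tmsfield <subcommand> [--config cfg.yaml] [--seed N] [--out dir]")
    return(2L)
  }
  cmd <- parsed$pos[1]
  handler <- switch(cmd,
    "make-head" = .cmd_make_head, "sample-placements" = .cmd_placements,
    "dadt" = .cmd_dadt, "solve" = .cmd_solve,
    "make-dataset" = .cmd_make_dataset, "train" = .cmd_train,
    "predict" = .cmd_predict, "evaluate" = .cmd_evaluate,
    "serve" = .cmd_serve,
    "client-demo" = .cmd_serve, "benchmark" = .cmd_benchmark,
    "reproduce-table2" = .cmd_table2, "demo" = .cmd_demo,
    NULL)
  if (is.null(handler)) {
    message(sprintf("unknown subcommand '%s'", cmd))
    return(2L)
  }
  cfg <- tryCatch(readRunConfig(parsed$flags$config),
                  error = function(e) e)
  if (inherits(cfg, "error")) {
    message(conditionMessage(cfg))
    return(1L)
  }
  if (!is.null(parsed$flags$seed) && !isTRUE(parsed$flags$seed)) {
    s <- as.integer(parsed$flags$seed)
    cfg$seed <- s
    cfg$placements$seed <- s
    cfg$train$seed <- s
    cfg$head$anisotropy_seed <- s
    cfg$streamlines$seed <- s
  }
  out <- if (is.null(parsed$flags$out) || isTRUE(parsed$flags$out)) "tmsfield-out"
         else parsed$flags$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  res <- tryCatch({
    handler(cfg, out, parsed$flags)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  res
}

.cmd_make_head <- function(cfg, out, flags) {
  hd <- .cli_head(cfg)
  writeNiftiVolume(hd$conductivity, file.path(out, "conductivity.nii.gz"))
  writeNiftiVolume(volumeGrid(array(as.numeric(hd$conductivity@mask),
                                    c(gridShape(hd$conductivity), 1L)),
                              gridAffine(hd$conductivity)),
                   file.path(out, "mask.nii.gz"))
  writeStl(hd$geometry@scalp_mesh, file.path(out, "scalp.stl"), "scalp")
  writeStl(hd$geometry@gm_mesh, file.path(out, "gm.stl"), "gm")
  sl <- makeSyntheticStreamlines(hd$geometry, cfg$streamlines$n,
                                 cfg$streamlines$points_per_line,
                                 cfg$streamlines$seed)
  writeStreamlinesJson(sl, file.path(out, "streamlines.json"))
  .cli_log("wrote head model artifacts to %s", out)
}

.cmd_placements <- function(cfg, out, flags) {
  hd <- .cli_head(cfg)
  pl <- samplePlacements(hd$geometry, cfg$placements$n_cases,
                         cfg$placements$n_directions, cfg$placements$seed,
                         cfg$placements$standoff_mm)
  writePlacementsCsv(pl, file.path(out, "placements.csv"))
  .cli_log("wrote %d placements to %s", length(pl@poses), out)
}

.cmd_dadt <- function(cfg, out, flags) {
  hd <- .cli_head(cfg)
  coil <- .cli_coil(cfg)
  pose <- .cli_pose(cfg, hd, flags)
  da <- dadtField(coil, pose, hd$conductivity)
  writeNiftiVolume(da, file.path(out, "dadt.nii.gz"))
  writeCoilStl(coil, file.path(out, "coil.stl"))
  .cli_log("wrote dA/dt field to %s", out)
}

.cmd_solve <- function(cfg, out, flags) {
  hd <- .cli_head(cfg)
  coil <- .cli_coil(cfg)
  pose <- .cli_pose(cfg, hd, flags)
  da <- dadtField(coil, pose, hd$conductivity)
  phi <- solvePotentialFdm(hd$conductivity, da, tol = cfg$solver$tol)
  E <- totalEfield(da, phi)
  writeNiftiVolume(da, file.path(out, "dadt.nii.gz"))
  writeNiftiVolume(phi, file.path(out, "phi.nii.gz"))
  writeNiftiVolume(E, file.path(out, "efield.nii.gz"))
  .cli_log("solved potential (residual %.2g, %d iterations)",
           phi@residual, phi@iterations)
}

.cli_pose <- function(cfg, hd, flags) {
  if (!is.null(flags$pose) && !isTRUE(flags$pose))
    return(readTransformText(flags$pose))
  pl <- samplePlacements(hd$geometry, 1L, cfg$placements$n_directions,
                         cfg$placements$seed, cfg$placements$standoff_mm)
  pl@poses[[1L]]
}

.cmd_make_dataset <- function(cfg, out, flags) {
  hd <- .cli_head(cfg)
  coil <- .cli_coil(cfg)
  pl <- samplePlacements(hd$geometry, cfg$placements$n_cases,
                         cfg$placements$n_directions, cfg$placements$seed,
                         cfg$placements$standoff_mm)
  ds <- makeTrainingDataset(hd$geometry, hd$conductivity, coil, pl,
                            fov_shape = cfg$fov_shape, tol = cfg$solver$tol,
                            verbose = TRUE)
  saveTrainingDataset(ds, file.path(out, "dataset.rds"))
  .cli_log("wrote %d training cases to %s", length(ds), out)
}

.cmd_train <- function(cfg, out, flags) {
  ds_path <- if (!is.null(flags$dataset) && !isTRUE(flags$dataset))
    flags$dataset else file.path(out, "dataset.rds")
  ds <- readTrainingDataset(ds_path)
  sc <- surrogateConfig(levels = cfg$train$levels,
                        base_channels = cfg$train$base_channels,
                        epochs = cfg$train$epochs,
                        batch_size = cfg$train$batch_size,
                        lr = cfg$train$lr, seed = cfg$train$seed)
  model <- trainSurrogate(ds, sc, verbose = TRUE)
  saveSurrogate(model, file.path(out, "model.rds"))
  writeHistoryCsv(model, file.path(out, "history.csv"))
  .cli_log("trained surrogate (final NE %.3f)", tail(model@history$ne, 1))
}

.cmd_predict <- function(cfg, out, flags) {
  model <- readSurrogate(if (!is.null(flags$model) && !isTRUE(flags$model))
    flags$model else file.path(out, "model.rds"))
  hd <- .cli_head(cfg)
  coil <- .cli_coil(cfg)
  pose <- .cli_pose(cfg, hd, flags)
  fov <- .fov_inputs(hd$geometry, hd$conductivity, coil, pose, cfg$fov_shape)
  pred <- predictEfield(model, fov$sigma, gridValues(fov$dadt))
  ef <- vectorField(gridValues(pred$efield), fov$affine)
  mg <- volumeGrid(gridValues(pred$magnitude), fov$affine)
  writeNiftiVolume(ef, file.path(out, "efield_pred.nii.gz"))
  writeNiftiVolume(mg, file.path(out, "efield_pred_mag.nii.gz"))
  .cli_log("wrote surrogate prediction to %s", out)
}

.cmd_evaluate <- function(cfg, out, flags) {
  model <- readSurrogate(if (!is.null(flags$model) && !isTRUE(flags$model))
    flags$model else file.path(out, "model.rds"))
  ds_path <- if (!is.null(flags$dataset) && !isTRUE(flags$dataset))
    flags$dataset else file.path(out, "dataset.rds")
  ds <- readTrainingDataset(ds_path)
  ev <- evaluateSurrogate(model, ds)
  write.csv(ev$per_case, file.path(out, "evaluation.csv"), row.names = FALSE)
  .cli_log("NE over %d case(s): %.3f +/- %.3f", nrow(ev$per_case), ev$mean, ev$sd)
}

.cmd_serve <- function(cfg, out, flags) {
  model <- readSurrogate(if (!is.null(flags$model) && !isTRUE(flags$model))
    flags$model else file.path(out, "model.rds"))
  hd <- .cli_head(cfg)
  coil <- .cli_coil(cfg)
  n <- cfg$serve$n_runs
  pl <- samplePlacements(hd$geometry, n, cfg$placements$n_directions,
                         cfg$placements$seed, cfg$placements$standoff_mm)
  ses <- runSession(model, hd$geometry, hd$conductivity, coil, pl@poses,
                    fov_shape = cfg$fov_shape)
  write.csv(ses$stats$runs, file.path(out, "session_runs.csv"), row.names = FALSE)
  .cli_log("served %d runs (%d image replies)", ses$stats$n_runs,
           length(ses$images))
}

.cmd_benchmark <- function(cfg, out, flags) {
  runs_path <- file.path(out, "session_runs.csv")
  if (!file.exists(runs_path)) stop("no session_runs.csv in --out; run 'serve' first")
  runs <- read.csv(runs_path)
  n <- if (!is.null(flags$runs) && !isTRUE(flags$runs)) as.integer(flags$runs)
       else min(nrow(runs), cfg$serve$n_runs)
  summ <- timePipeline(runs, runs = n)
  write.csv(summ, file.path(out, "timing_summary.csv"), row.names = FALSE)
  .cli_log("cnn %.4f +/- %.4f s, vis %.4f +/- %.4f s over %d runs",
           summ$mean_seconds[1], summ$sd_seconds[1],
           summ$mean_seconds[2], summ$sd_seconds[2], n)
}

.cmd_table2 <- function(cfg, out, flags) {
  report <- reproduceTable2()
  writeTable2Report(report, out)
  .cli_log("t(%d) = %.1f, mean improvement %.2fx (printed)",
           report$ttest$df, report$ttest$t, report$mean_improvement_printed)
}

# end-to-end smoke demo at a deliberately tiny problem size
.cmd_demo <- function(cfg, out, flags) {
  cfg$head$outer_radius_mm <- 40
  cfg$head$grid_shape <- c(32L, 32L, 32L)
  cfg$head$voxel_mm <- 3
  cfg$fov_shape <- c(16L, 16L, 16L)
  cfg$placements$n_cases <- 12L
  cfg$train$epochs <- 30L
  cfg$train$base_channels <- 4L
  cfg$serve$n_runs <- 5L
  cfg$streamlines$n <- 10L
  .cmd_make_head(cfg, out, flags)
  .cmd_placements(cfg, out, flags)
  .cmd_make_dataset(cfg, out, flags)
  .cmd_train(cfg, out, flags)
  .cmd_evaluate(cfg, out, flags)
  .cmd_serve(cfg, out, flags)
  .cmd_benchmark(cfg, out, list(runs = "5"))
  .cmd_table2(cfg, out, flags)
  .cli_log("demo complete; artifacts in %s", out)
}
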