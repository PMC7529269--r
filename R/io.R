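# Export formats, run manifests and pipeline orchestration.

#' Write a nodal field as a legacy-ASCII VTK structured-points file
#'
#' @param fields named list of length-N nodal vectors
#' @param grid a `grid2d`
#' @param path output file
#' @export
write_vtk_structured <- function(fields, grid, path) {
  stopifnot(length(fields) >= 1, !is.null(names(fields)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "cardioROM field export",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", grid$nx, grid$ny),
               "ORIGIN 0 0 0",
               sprintf("SPACING %.10g %.10g 1", grid$hx, grid$hy),
               sprintf("POINT_DATA %d", grid$N)), con)
  for (nm in names(fields)) {
    v <- fields[[nm]]
    stopifnot(length(v) == grid$N)
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(format(v, digits = 10, scientific = TRUE, trim = TRUE), con)
  }
  invisible(path)
}

#' Write probe AP traces to CSV (columns t_ms, u_mV per probe)
#' @param traj a `fom_trajectory` solved with probes
#' @param path output CSV path
#' @export
write_probe_csv <- function(traj, path) {
  if (is.null(traj$probes)) stop("trajectory has no probe traces")
  utils::write.csv(traj$probes, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a snapshot set (RDS blob + JSON metadata sidecar)
#' @param snaps a `snapshot_set`
#' @param path `.rds` path
#' @export
save_snapshots <- function(snaps, path) {
  saveRDS(snaps, path)
  meta <- list(scenario = snaps$scenario_name, N = nrow(snaps$S),
               Ns = ncol(snaps$S), Nt = snaps$time$Nt,
               n_params = nrow(snaps$params))
  jsonlite::write_json(meta, sub("\\.rds$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_snapshots
#' @export
load_snapshots <- function(path) readRDS(path)

#' Reproducibility manifest for a pipeline run
#' @param config the run config (list)
#' @param seed master seed
#' @return list with package version, timestamp, config and a config hash
#' @export
run_manifest <- function(config, seed) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(list(config = config, seed = seed), tmp,
                       auto_unbox = TRUE, digits = NA)
  list(
    package = "cardioROM",
    version = as.character(utils::packageVersion("cardioROM")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    config_hash = unname(tools::md5sum(tmp))
  )
}

#' Run the snapshot -> ROM -> evaluation pipeline
#'
#' Stages: generate snapshots for the scenario's training/testing parameter
#' grids (cached in `out_dir` and reused on re-runs), optionally build and
#' evaluate the POD-Galerkin ROM and/or train and evaluate the DL-ROM on the
#' testing set, then write `report.json` with the error indicators and
#' informational timings, plus a reproducibility manifest.
#'
#' @param config list (or path to a YAML file) with fields `scenario` (preset
#'   name), optional `overrides` (builder arguments), `seed`, and optional
#'   `pod` (`eps_pod`/`n_fixed`, `eps_deim`/`m_fixed`, `Nc`) and `dlrom`
#'   (`n`, `conv_channels`, `kernel`, `stride`, `dfnn_hidden` + any
#'   [train_config()] fields) blocks
#' @param out_dir artifact directory
#' @return the report list, invisibly; artifacts on disk
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$scenario))
  seed <- config$seed %||% 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sc <- scenario_from_config(list(builder = config$scenario,
                                  args = config$overrides %||% list()))
  manifest <- run_manifest(config, seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  snap_path <- file.path(out_dir, "snapshots.rds")
  if (file.exists(snap_path)) {
    snaps <- load_snapshots(snap_path)
  } else {
    snaps <- snapshot_set(sc, sc$train_params)
    save_snapshots(snaps, snap_path)
  }
  test_path <- file.path(out_dir, "snapshots_test.rds")
  if (file.exists(test_path)) {
    test_runs <- readRDS(test_path)
  } else {
    test_runs <- lapply(seq_len(nrow(sc$test_params)),
                        function(i) solve_fom(sc, sc$test_params[i, ])$U)
    saveRDS(test_runs, test_path)
  }

  report <- list(scenario = sc$name, seed = seed,
                 manifest_hash = manifest$config_hash,
                 N = sc$grid$N, Nt = sc$time$Nt,
                 n_train = nrow(sc$train_params),
                 n_test = nrow(sc$test_params))

  if (!is.null(config$pod)) {
    pc <- config$pod
    t0 <- proc.time()[3]
    pod <- build_pod_rom(snaps,
                         eps_pod = pc$eps_pod %||% 1e-3,
                         n_fixed = pc$n_fixed,
                         eps_deim = pc$eps_deim,
                         m_fixed = pc$m_fixed,
                         Nc = pc$Nc %||% 1, seed = seed)
    saveRDS(pod, file.path(out_dir, "pod_model.rds"))
    pred <- lapply(seq_len(nrow(sc$test_params)), function(i)
      solve_pod_rom(pod, sc, sc$test_params[i, ])$U)
    report$pod <- list(
      Nc = pod$Nc,
      n = vapply(pod$clusters, function(cl) cl$n, numeric(1)),
      m = vapply(pod$clusters, function(cl) cl$m, numeric(1)),
      eps_rel = eps_rel(test_runs, pred),
      seconds = round(proc.time()[3] - t0, 2))
  }

  if (!is.null(config$dlrom)) {
    dc <- config$dlrom
    t0 <- proc.time()[3]
    ds <- prepare_dataset(snaps)
    arch <- dlrom_architecture(
      n = dc$n %||% (ncol(sc$param_box) + 1), n_mu = ncol(sc$param_box),
      image_side = ds$s,
      conv_channels = dc$conv_channels %||% c(8, 16, 32, 64),
      kernel = dc$kernel %||% 5, stride = dc$stride %||% 2,
      dfnn_hidden = dc$dfnn_hidden %||% rep(50L, 4))
    cfg_fields <- intersect(names(dc), names(formals(train_config)))
    cfg <- do.call(train_config,
                   utils::modifyList(setNames(lapply(cfg_fields, function(f) dc[[f]]),
                                              cfg_fields),
                                     list(seed = seed)))
    model <- train_dlrom(ds, arch, cfg)
    save_dlrom(model, file.path(out_dir, "dlrom"))
    pred <- lapply(seq_len(nrow(sc$test_params)), function(i)
      predict_trajectory(model, sc$time$sample_times, sc$test_params[i, ]))
    report$dlrom <- list(
      n = arch$n, epochs = nrow(model$history),
      best_val_loss = model$best_val_loss,
      eps_rel = eps_rel(test_runs, pred),
      seconds = round(proc.time()[3] - t0, 2))
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
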