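default_config <- function() {
  list(
    seed = 1L,
    out = "sls_out",
    scene = list(n_cells = 12L, fov = c(72L, 72L), duration = 90,
                 pixel_size = 0.77, firing_rate = 0.29,
                 stimulus_enabled = FALSE, bout_rate = 0,
                 neuropil_gain = 0.25),
    acquisition = list(raster_fs = 1.0,
                       raster_frames = 60L, dwell = 4.4e-6,
                       surround = 1L, sls_duration = 20),
    analysis = list(strategy = "global", alpha = 0.7,
                    artifact_threshold = 0.3, window = 10,
                    bin = 0.5, n_surrogates = 1000L, coactivity_alpha = 0.05)
  )
}

#' Read, validate and write pipeline configurations
#'
#' Configurations are YAML with the three sections `scene`, `acquisition`
#' and `analysis` plus top-level `seed` and `out`. Unknown keys are
#' rejected; missing keys take the documented defaults. Round-trips are
#' lossless.
#'
#' @param path YAML file.
#' @return validated config list of class `sls_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("no such config file: %s", path)
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config a (partial) config list.
#' @export
validate_config <- function(config) {
  def <- default_config()
  bad <- setdiff(names(config), names(def))
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  for (sec in c("scene", "acquisition", "analysis")) {
    if (!is.null(config[[sec]])) {
      bad <- setdiff(names(config[[sec]]), names(def[[sec]]))
      if (length(bad))
        stopf("unknown key(s) in '%s': %s", sec, paste(bad, collapse = ", "))
    }
  }
  out <- utils::modifyList(def, config)
  class(out) <- "sls_config"
  out
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  # the output path is provenance, not science: exclude it so reruns into
  # different directories stamp identically
  cfg <- unclass(config)
  cfg$out <- NULL
  content_hash(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA))
}

write_stamped_json <- function(obj, path, hash) {
  obj$config_hash <- hash
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  close(con)
}

#' Run the end-to-end simulated SLS pipeline
#'
#' simulate -> reference raster -> SNR segmentation -> trajectory -> SLS
#' acquisition -> artifact screening -> extraction -> neuropil correction
#' -> dF/F0 + event detection -> ensembles. All intermediates are written
#' under `config$out` and stamped with the config hash; re-running the
#' same config reproduces every output bit-identically.
#'
#' @param config an `sls_config` (see [read_config()]) or partial list.
#' @param quiet suppress progress messages.
#' @return list of result objects (scene, selections, trajectory,
#'   recording, traces, events, ensembles, paths), invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "sls_config")) config else validate_config(config)
  hash <- config_hash(cfg)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s (partial outputs kept in %s)",
            name, conditionMessage(e), cfg$out))
  }

  say("[simulate] scene seed %d", cfg$seed)
  sc <- cfg$scene
  scene <- stage("simulate", {
    make_scene(scene_params(
      fov = sc$fov, n_cells = sc$n_cells, duration = sc$duration,
      pixel_size = sc$pixel_size, firing_rate = sc$firing_rate,
      neuropil_gain = sc$neuropil_gain,
      motion = list(bout_rate = sc$bout_rate),
      stimulus = list(enabled = isTRUE(sc$stimulus_enabled)),
      seed = cfg$seed))
  })

  acq <- cfg$acquisition
  raster_dwell <- 1 / (acq$raster_fs * prod(sc$fov))
  say("[acquire] reference raster: %d frames", acq$raster_frames)
  ref <- stage("acquire-raster",
               acquire_raster(scene, raster_dwell, acq$raster_frames))
  write_tseries(ref, file.path(cfg$out, "reference.tif"))

  say("[segment] %d cells", nrow(scene$cells))
  sels <- stage("segment", lapply(seq_len(nrow(scene$cells)), function(i) {
    box <- cell_box(round(scene$cells$x[i]), round(scene$cells$y[i]),
                    pixel_size = sc$pixel_size, fov = sc$fov)
    select_pixels(ref, box)
  }))

  say("[trace] surround %d", acq$surround)
  traj <- stage("trace", build_trajectory(sels, acq$surround, acq$dwell,
                                          fov = sc$fov, seed = cfg$seed))
  write_trajectory(traj, file.path(cfg$out, "trajectory.xml"))

  n_scans <- floor(min(acq$sls_duration, sc$duration) / traj$scan_period)
  say("[acquire] SLS: %d scans @ %.1f Hz", n_scans, 1 / traj$scan_period)
  rec <- stage("acquire-sls", acquire_sls(scene, traj, n_scans))

  say("[extract] pixel groups + traces")
  assign <- stage("extract", assign_pixel_groups(
    traj, lapply(sels, function(s) s$selected)))
  traces <- stage("extract", extract_traces(rec, assign))

  an <- cfg$analysis
  report <- stage("motion", detect_large_artifacts(
    rec, threshold = an$artifact_threshold, window = min(an$window, n_scans / rec$fs / 2)))
  write_stamped_json(list(detections = report$detections,
                          truncation_index = report$truncation_index,
                          var_frac = report$var_frac),
                     file.path(cfg$out, "artifact_report.json"), hash)

  corr <- stage("neuropil", {
    if (an$strategy == "global" && nrow(traces$global_np) < 2)
      list(corrected = traces$roi, model = NULL)
    else correct_neuropil(traces, an$strategy, an$alpha)
  })

  say("[analyze] events + ensembles")
  n_roi <- nrow(corr$corrected)
  evl <- list(); dffs <- vector("list", n_roi)
  for (i in seq_len(n_roi)) {
    d <- dff(pmax(corr$corrected[i, ], 1))
    dffs[[i]] <- d
    evl[[i]] <- detect_events(d, rec$fs, roi = i)
  }
  events <- do.call(rbind, evl)
  events <- classify_event_size(events)
  den <- t(vapply(dffs, function(d)
    suppressWarnings(denoise_nonneg(d, rec$fs)),
    numeric(ncol(corr$corrected))))
  raster <- binarize_activity(den, fs = rec$fs)
  kstar <- coactivity_threshold(raster, n_surrogates = an$n_surrogates,
                                alpha = an$coactivity_alpha, seed = cfg$seed)
  ens <- detect_ensembles(raster, kstar, fs = rec$fs)

  tidy <- do.call(rbind, lapply(seq_len(n_roi), function(i)
    data.frame(roi = i, scan = seq_len(ncol(traces$roi)),
               time = rec$t0, raw = traces$roi[i, ],
               corrected = corr$corrected[i, ], dff = dffs[[i]]$dff)))
  write_stamped_csv(tidy, file.path(cfg$out, "traces.csv"), hash)
  write_stamped_csv(events, file.path(cfg$out, "events.csv"), hash)
  write_stamped_json(list(k_star = kstar, rate = ens$rate,
                          n_ensembles = length(ens$frames),
                          frames = ens$frames),
                     file.path(cfg$out, "ensembles.json"), hash)
  write_config(cfg, file.path(cfg$out, "config_echo.yaml"))
  write_stamped_json(list(files = list.files(cfg$out)),
                     file.path(cfg$out, "provenance.json"), hash)
  say("[done] outputs in %s (config hash %s)", cfg$out, hash)
  invisible(list(scene = scene, reference = ref, selections = sels,
                 trajectory = traj, recording = rec, traces = traces,
                 corrected = corr$corrected, events = events,
                 ensembles = ens, config = cfg, hash = hash))
}
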