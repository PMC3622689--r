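#' Configuration of a full processing run
#'
#' Bundles every tunable of the segment -> quantify -> track pipeline.
#' Defaults follow the package's standard operating values: 1.5 uM
#' therapeutic threshold, 10 px linking radius, 1000-iteration cap for
#' the locally-adaptive thresholder, 75 s frame interval.
#'
#' @param input A [channel_stack()], or a path to a multi-page TIFF.
#' @param channels Channel names for [read_stack()] when `input` is a
#'   path.
#' @param nuclear_channel,drug_channel Channel roles.
#' @param axis `"time"` or `"z"`.
#' @param frame_interval_s Seconds per frame (path input only).
#' @param calibration A `CalibrationCurve`, or a path to a CSV with
#'   columns `concentration_uM`, `fluorescence`.
#' @param segmentation A [segmentation_params()] object.
#' @param therapeutic_threshold_uM Subtherapeutic cutoff (uM).
#' @param max_radius Track linking radius (px).
#' @param ring_radius Cytosolic ring dilation radius (px).
#' @param vessel_roi `c(row1, row2, col1, col2)` or `NULL` to skip the
#'   vessel curve.
#' @param register If `TRUE`, translational drift is corrected on the
#'   nuclear channel before segmentation.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when `input` is generated
#'   upstream).
#' @return An object of class `RunConfig`.
#' @export
run_config <- function(input, channels = c("nuclear", "drug"),
                       nuclear_channel = "nuclear", drug_channel = "drug",
                       axis = "time", frame_interval_s = 75,
                       calibration, segmentation = segmentation_params(),
                       therapeutic_threshold_uM = 1.5, max_radius = 10,
                       ring_radius = 5L, vessel_roi = NULL,
                       register = FALSE, seed = 1L) {
  if (is.character(input) && !file.exists(input)) {
    stop(sprintf("config field 'input': file '%s' not found", input))
  }
  if (is.character(calibration)) {
    if (!file.exists(calibration)) {
      stop(sprintf("config field 'calibration': file '%s' not found",
                   calibration))
    }
  } else if (!inherits(calibration, "CalibrationCurve")) {
    stop("config field 'calibration': need a CalibrationCurve or a CSV path")
  }
  stopifnot(inherits(segmentation, "SegmentationParams"),
            therapeutic_threshold_uM >= 0, max_radius > 0, ring_radius >= 1)
  structure(list(input = input, channels = channels,
                 nuclear_channel = nuclear_channel,
                 drug_channel = drug_channel, axis = axis,
                 frame_interval_s = frame_interval_s,
                 calibration = calibration, segmentation = segmentation,
                 therapeutic_threshold_uM = therapeutic_threshold_uM,
                 max_radius = max_radius, ring_radius = as.integer(ring_radius),
                 vessel_roi = vessel_roi, register = isTRUE(register),
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Load a run configuration from a YAML file
#'
#' Recognized keys mirror the [run_config()] arguments; segmentation
#' and locally-adaptive thresholding parameters live under
#' `segmentation:` (keys `gamma`, `min_object_area`,
#' `speckle_disk_radius`, `method`, `invert`, `ray_iterations`,
#' `ray_power`, `ray_epsilon`, `ray_window`).
#'
#' @param path YAML file path.
#' @param overrides Named list overriding top-level keys (CLI flags).
#' @return A `RunConfig`.
#' @export
load_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  y <- yaml::read_yaml(path)
  y[names(overrides)] <- overrides
  sp <- y$segmentation
  seg <- segmentation_params(
    gamma = sp$gamma %||% 1,
    min_object_area = sp$min_object_area %||% 40L,
    speckle_disk_radius = sp$speckle_disk_radius %||% 1L,
    method = sp$method %||% "ray",
    invert = isTRUE(sp$invert),
    ray = ray_params(iterations = sp$ray_iterations %||% 1000L,
                     power = sp$ray_power %||% 1,
                     epsilon = sp$ray_epsilon %||% 1e-4,
                     window_radius = sp$ray_window %||% 15L))
  run_config(input = y$input,
             channels = y$channels %||% c("nuclear", "drug"),
             nuclear_channel = y$nuclear_channel %||% "nuclear",
             drug_channel = y$drug_channel %||% "drug",
             axis = y$axis %||% "time",
             frame_interval_s = y$frame_interval_s %||% 75,
             calibration = y$calibration,
             segmentation = seg,
             therapeutic_threshold_uM = y$therapeutic_threshold_uM %||% 1.5,
             max_radius = y$max_radius %||% 10,
             ring_radius = y$ring_radius %||% 5L,
             vessel_roi = if (!is.null(y$vessel_roi)) as.integer(y$vessel_roi),
             register = isTRUE(y$register),
             seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Segments every frame of the nuclear channel, converts per-cell drug
#' fluorescence to concentrations, computes the vessel curve and the
#' per-frame subtherapeutic fraction, links cells into tracks, and
#' writes all outputs plus a JSON run manifest that records every
#' parameter. Identical configuration and input produce byte-identical
#' CSV outputs.
#'
#' Files written to `out_dir`: `regions.csv`, `per_frame.csv`,
#' `per_cell.csv`, `tracks.csv`, `labels.tif` (16-bit label maps),
#' `manifest.json`, `run.log`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress progress messages to stderr.
#' @return Invisibly, a list with the in-memory results: `segmented`,
#'   `series`, `vessel`, `tracks`, `nuclear_fraction`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  t_all <- proc.time()[["elapsed"]]
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    writeLines(msg, log_con)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    say("stage %-10s %.2fs", name, proc.time()[["elapsed"]] - t0)
    out
  }

  stack <- stage("load", {
    if (is.character(config$input)) {
      read_stack(config$input, config$channels, axis = config$axis,
                 frame_interval_s = config$frame_interval_s)
    } else config$input
  })
  if (config$register && n_frames(stack) > 1L) {
    reg <- stage("register",
                 register_translation(stack, config$nuclear_channel))
    stack <- reg$stack
  }
  curve <- stage("calibrate", {
    if (is.character(config$calibration)) {
      fit_calibration(utils::read.csv(config$calibration))
    } else config$calibration
  })
  seg <- stage("segment",
               segment_stack(stack, config$segmentation,
                             config$nuclear_channel))
  series <- stage("quantify",
                  cell_concentrations(seg$frames, stack,
                                      config$drug_channel, curve))
  vessel <- if (!is.null(config$vessel_roi)) {
    stage("vessel", vessel_curve(stack, config$drug_channel,
                                 config$vessel_roi, curve))
  }
  tracks <- stage("track", {
    tr <- link_tracks(regions_to_detections(seg$frames), config$max_radius)
    if (!is.null(series$per_cell)) attach_concentrations(tr, series) else tr
  })
  nf_frac <- stage("partition", {
    last <- n_frames(stack)           # steady state: last frame
    lr <- seg$frames[[last]]
    if (nrow(lr$regions)) {
      nuclear_fraction(lr, get_frame(stack, config$drug_channel, last),
                       config$ring_radius)
    } else NA_real_
  })

  # --- outputs --------------------------------------------------------
  per_frame <- series$per_frame
  if (!is.null(vessel)) per_frame$vessel_uM <- vessel$vessel_uM
  sub <- vapply(per_frame$frame, function(fi) {
    pc <- series$per_cell
    if (is.null(pc)) return(NA_real_)
    subtherapeutic_fraction(pc$conc_uM[pc$frame == fi],
                            config$therapeutic_threshold_uM)
  }, numeric(1))
  per_frame$frac_subtherapeutic <- sub

  regions <- do.call(rbind, lapply(seq_along(seg$frames), function(fi) {
    r <- seg$frames[[fi]]$regions
    if (!nrow(r)) return(NULL)
    cbind(frame = fi, r)
  }))
  paths <- c(regions = "regions.csv", per_frame = "per_frame.csv",
             per_cell = "per_cell.csv", tracks = "tracks.csv",
             labels = "labels.tif", manifest = "manifest.json",
             log = "run.log")
  utils::write.csv(regions, file.path(out_dir, paths["regions"]),
                   row.names = FALSE)
  utils::write.csv(per_frame, file.path(out_dir, paths["per_frame"]),
                   row.names = FALSE)
  utils::write.csv(series$per_cell, file.path(out_dir, paths["per_cell"]),
                   row.names = FALSE)
  utils::write.csv(tracks, file.path(out_dir, paths["tracks"]),
                   row.names = FALSE)
  tiff::writeTIFF(lapply(seg$frames, function(f) f$label_map / 65535),
                  file.path(out_dir, paths["labels"]), bits.per.sample = 16)

  manifest <- list(
    package = "ivpharm",
    version = as.character(utils::packageVersion("ivpharm")),
    seed = config$seed,
    parameters = list(
      nuclear_channel = config$nuclear_channel,
      drug_channel = config$drug_channel,
      axis = stack$axis,
      frame_interval_s = stack$frame_interval_s,
      gamma = config$segmentation$gamma,
      method = config$segmentation$method,
      min_object_area = config$segmentation$min_object_area,
      speckle_disk_radius = config$segmentation$speckle_disk_radius,
      invert = config$segmentation$invert,
      ray = unclass(config$segmentation$ray),
      calibration = list(slope = curve$slope, intercept = curve$intercept,
                         r_squared = curve$r_squared),
      therapeutic_threshold_uM = config$therapeutic_threshold_uM,
      max_radius = config$max_radius,
      ring_radius = config$ring_radius,
      vessel_roi = config$vessel_roi,
      register = config$register),
    n_frames = n_frames(stack),
    n_tracks = length(unique(tracks$track_id)),
    nuclear_fraction_last_frame = nf_frac,
    outputs = as.list(paths))
  jsonlite::write_json(manifest, file.path(out_dir, paths["manifest"]),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  say("total %.2fs", proc.time()[["elapsed"]] - t_all)
  invisible(list(segmented = seg, series = series, vessel = vessel,
                 tracks = tracks, nuclear_fraction = nf_frac,
                 manifest = manifest))
}

#' Render a segmentation preview overlay
#'
#' Draws the frame in gray with region borders in green and writes a
#' PNG — the scriptable equivalent of the interactive tune-and-review
#' loop: adjust parameters, re-render, repeat until satisfied, then
#' process the whole movie with the chosen values.
#'
#' @param stack A [channel_stack()].
#' @param params [segmentation_params()] (its `frame_index` selects the
#'   previewed frame).
#' @param channel Channel to segment.
#' @param path Output PNG path.
#' @return The `LabeledRegions` of the previewed frame, invisibly.
#' @export
preview_frame <- function(stack, params, channel, path) {
  lr <- segment_frame(stack, params, channel)
  fr <- get_frame(stack, channel, params$frame_index)
  rgb <- array(rep(fr, 3), c(dim(fr), 3))
  if (nrow(lr$regions)) {
    b <- region_borders(lr$label_map)
    rgb[, , 1][b] <- 0
    rgb[, , 2][b] <- 1
    rgb[, , 3][b] <- 0
  }
  png::writePNG(rgb, path)
  invisible(lr)
}
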