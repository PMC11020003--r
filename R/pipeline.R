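#' Default demo pipeline configuration
#'
#' A small, fully synthetic end-to-end run: simulate a cohort and a marker
#' video, preprocess, extract features, cross-validate a classifier, track
#' the marker and render probability overlays. All randomness derives from
#' `seed`.
#'
#' @param out_dir Artifact directory.
#' @param seed Integer master seed.
#' @return A run-config list (see [validate_run_config()]).
#' @export
demo_config <- function(out_dir = tempfile("drspec_demo_"), seed = 7L) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    input = list(mode = "simulate"),
    simulate = list(n_patients = 6, spectra_per_class_per_patient = 12),
    grid = list(start = 450, stop = 1000, n_points = 1922),
    mad_factor = 1.5,
    classifier = list(kind = "rf", folds = 3, use_intensities = FALSE),
    tracking = list(
      n_frames = 40, trajectory = "linear", marker_radius = 9,
      occlude_fraction = 0.1, q = 1, r = 2
    ),
    overlay = list(alpha = 0.6, n_sites = 6)
  )
}

#' Validate a run configuration
#'
#' Structural validation before any compute: required blocks and types,
#' ranges, and -- in `files` input mode -- existence of the spectra and
#' white/dark reference paths.
#'
#' @param config Run-config list (or path to a JSON file).
#' @return The validated config, invisibly a list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  fail <- function(msg) abort(paste0("config: ", msg), class = "drspec_config_error")
  if (!is.list(config)) fail("must be a list or JSON object")
  for (f in c("seed", "out_dir", "input", "grid", "classifier", "tracking")) {
    if (is.null(config[[f]])) fail(sprintf("missing required field '%s'", f))
  }
  if (!is.numeric(config$seed)) fail("seed must be numeric")
  mode <- config$input$mode %||% "simulate"
  if (!(mode %in% c("simulate", "files"))) fail("input.mode must be 'simulate' or 'files'")
  if (mode == "files") {
    for (f in c("spectra", "white", "dark")) {
      if (is.null(config$input[[f]])) {
        fail(sprintf("input.%s path required in files mode", f))
      }
    }
    for (f in c("spectra", "white", "dark")) {
      p <- config$input[[f]]
      if (!file.exists(p)) fail(sprintf("input.%s path does not exist: %s", f, p))
    }
  } else if (is.null(config$simulate)) {
    fail("simulate block required in simulate mode")
  }
  g <- config$grid
  if (!(g$start < g$stop) || g$n_points < 2) fail("invalid grid block")
  if (!(config$classifier$kind %in% c("specnet", "rf", "xgb", "svm", "mlp"))) {
    fail("unsupported classifier.kind")
  }
  invisible(config)
}

#' Run the end-to-end demo pipeline
#'
#' Stages, in order: simulate (or load) spectra -> preprocess (calibrate,
#' resample, outlier-reject, SNV) -> extract features -> patient-wise
#' cross-validated classification -> marker-video tracking -> graduated
#' probability overlay. Each stage logs one line; every artifact lands in
#' `config$out_dir`. Outputs contain no timestamps, so a rerun with the
#' same config is byte-identical.
#'
#' @param config Run-config list or JSON path (see [demo_config()]).
#' @param quiet Suppress stage logging.
#' @return Invisibly, a list of artifact paths and the CV summary.
#' @export
run_pipeline <- function(config = demo_config(), quiet = FALSE) {
  config <- validate_run_config(config)
  log_stage <- function(...) if (!quiet) message(sprintf(...))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed)
  log_stage("[simulate] seed=%d", seed)
  if ((config$input$mode %||% "simulate") == "simulate") {
    spec <- synthetic_dataset_spec(
      n_patients = config$simulate$n_patients,
      spectra_per_class_per_patient = config$simulate$spectra_per_class_per_patient,
      seed = seed
    )
    raw <- generate_dataset(spec)
    refs <- raw$refs
  } else {
    raw <- read_spectra(config$input$spectra)
    refs <- reference_set(
      white = read_spectra(config$input$white),
      dark = read_spectra(config$input$dark)
    )
  }
  grid <- wavelength_grid(config$grid$start, config$grid$stop, config$grid$n_points)
  log_stage("[preprocess] %d spectra -> grid %d points, MAD factor %g",
            n_spectra(raw), grid$n_points, config$mad_factor %||% 1.5)
  proc <- preprocess_set(raw, refs, grid, mad_factor = config$mad_factor %||% 1.5)
  rep <- attr(proc, "outlier_report")
  utils::write.table(rep, file.path(out_dir, "outlier_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_spectra(proc, file.path(out_dir, "processed.drsspec"))
  log_stage("[features] extracting shape features for %d spectra", n_spectra(proc))
  feats <- extract_features(proc)
  utils::write.table(feats, file.path(out_dir, "features.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  kind <- config$classifier$kind
  use_int <- isTRUE(config$classifier$use_intensities)
  x <- if (kind == "specnet") {
    proc$intensities
  } else {
    fm <- as.matrix(feats[, c("peak1_intensity", "peak1_wavelength",
                              "peak2_intensity", "peak2_wavelength",
                              "band_mean_480_550", "band_mean_580_700",
                              "band_mean_450_720", "hb_saturation")])
    fm[is.na(fm)] <- 0.5
    if (use_int) cbind(fm, proc$intensities) else fm
  }
  k <- config$classifier$folds %||% 5
  log_stage("[train/evaluate] %s, %d-fold patient-wise CV, seed=%d", kind, k, seed)
  cv <- cross_validate(x, proc$meta, kind = kind, k = k, seed = seed,
                       config = if (kind == "specnet") {
                         specnet_config(n1 = ncol(x), epochs = 20, seed = seed)
                       })
  summ <- tidy(cv)
  metrics <- stats::setNames(as.list(summ$mean), summ$metric)
  metrics$per_fold <- as.data.frame(cv[, c("fold", "accuracy", "sensitivity",
                                           "specificity", "auc")])
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("[track] %d frames, %s trajectory", config$tracking$n_frames,
            config$tracking$trajectory)
  scene <- marker_scene_spec(
    n_frames = config$tracking$n_frames,
    trajectory = config$tracking$trajectory,
    marker_radius = config$tracking$marker_radius %||% 9,
    seed = seed
  )
  set.seed(seed + 1)
  occ <- sort(sample.int(scene$n_frames,
                         round((config$tracking$occlude_fraction %||% 0) * scene$n_frames)))
  vid <- generate_marker_frames(scene, occlude_frames = occ)
  traj <- track_sequence(vid$frames, q = config$tracking$q %||% 1,
                         r = config$tracking$r %||% 2)
  utils::write.table(traj, file.path(out_dir, "trajectory.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  log_stage("[overlay] rendering %d classification sites",
            config$overlay$n_sites %||% 6)
  # one site per (patient, label) group, mean refit probability, placed
  # at evenly spaced tracked positions
  model <- train_classifier(x, proc$meta$label, kind = kind, seed = seed,
                            config = if (kind == "specnet") {
                              specnet_config(n1 = ncol(x), epochs = 20, seed = seed)
                            })
  probs <- predict_proba(model, x)
  grp <- proc$meta %>%
    mutate(p = probs) %>%
    group_by(.data$patient_id, .data$label) %>%
    summarise(p = mean(.data$p), .groups = "drop")
  n_sites <- min(config$overlay$n_sites %||% 6, nrow(grp))
  ok <- which(!is.na(traj$x))
  pick <- ok[round(seq(1, length(ok), length.out = n_sites))]
  sites <- tibble(
    x = traj$x[pick], y = traj$y[pick],
    tumour_probability = grp$p[seq_len(n_sites)],
    radius = 8
  )
  frame_sel <- pick
  overlay_paths <- character(0)
  for (j in seq_along(frame_sel)) {
    fr <- render_overlay(vid$frames[[frame_sel[j]]], sites[seq_len(j), ],
                         alpha = config$overlay$alpha %||% 0.6)
    p <- file.path(out_dir, sprintf("overlay_%04d.png", frame_sel[j]))
    png::writePNG(fr, p)
    overlay_paths <- c(overlay_paths, p)
  }
  log_stage("[done] artifacts in %s", out_dir)
  invisible(list(
    out_dir = out_dir,
    metrics = file.path(out_dir, "metrics.json"),
    trajectory = file.path(out_dir, "trajectory.tsv"),
    features = file.path(out_dir, "features.tsv"),
    overlays = overlay_paths,
    cv_summary = summ
  ))
}
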