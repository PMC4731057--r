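#' Pipeline configuration
#'
#' Collects every tunable parameter of the workflow in one validated
#' list: grid, preprocessing-chain parameters, intensity threshold,
#' panel size, selector parameters, calibrator hyperparameters and the
#' master seed.  Values not supplied keep their defaults.
#'
#' @param ... named overrides of the defaults (see Details).
#' @details Defaults: grid 2000--20000 with 30000 bins; alignment
#'   `max_shift_bins = 50`; baseline `half_window_bins = 250`; smoothing
#'   `window_bins = 21`, `polyorder = 3`; `normalize_mode = "sum"`;
#'   `threshold = 1e-3`; `panel_size = 10`; selectors `cv_folds = 5`,
#'   `spls_components = 2`, `sparsity = 0.8`; calibrators `n_hidden = 4`,
#'   `epochs = 3000`, `learning_rate = 0.01`, `momentum = 0.9`,
#'   `pls_components = 5`; `seed = 1`.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(grid_lo = 2000, grid_hi = 20000, grid_bins = 30000,
              max_shift_bins = 50, half_window_bins = 250,
              window_bins = 21, polyorder = 3, normalize_mode = "sum",
              threshold = 1e-3, panel_size = 10,
              cv_folds = 5, spls_components = 2, sparsity = 0.8,
              n_hidden = 4, epochs = 3000, learning_rate = 0.01,
              momentum = 0.9, pls_components = 5, seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(cfg, over)
  validate_config(cfg)
}

#' @rdname pipeline_config
#' @param path YAML file whose top-level keys override the defaults.
#' @export
read_config <- function(path) {
  over <- yaml::read_yaml(path)
  if (is.null(over)) over <- list()
  do.call(pipeline_config, over)
}

#' @rdname pipeline_config
#' @param cfg a configuration list.
#' @export
validate_config <- function(cfg) {
  problems <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(cfg$grid_lo < cfg$grid_hi, "grid_lo must be < grid_hi")
  chk(cfg$grid_bins >= 2, "grid_bins must be >= 2")
  chk(cfg$max_shift_bins >= 0 && cfg$max_shift_bins < cfg$grid_bins,
      "max_shift_bins must be in [0, grid_bins)")
  chk(cfg$half_window_bins >= 1, "half_window_bins must be >= 1")
  chk(cfg$window_bins %% 2 == 1, "window_bins must be odd")
  chk(cfg$polyorder < cfg$window_bins, "polyorder must be < window_bins")
  chk(cfg$threshold >= 0, "threshold must be >= 0")
  chk(cfg$panel_size >= 1, "panel_size must be >= 1")
  chk(cfg$cv_folds >= 2, "cv_folds must be >= 2")
  chk(cfg$sparsity >= 0 && cfg$sparsity < 1, "sparsity must be in [0, 1)")
  chk(cfg$n_hidden >= 1, "n_hidden must be >= 1")
  chk(cfg$epochs >= 1, "epochs must be >= 1")
  chk(cfg$learning_rate > 0, "learning_rate must be > 0")
  chk(cfg$momentum >= 0 && cfg$momentum < 1, "momentum must be in [0, 1)")
  if (length(problems))
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Simulate a calibration dataset to disk
#'
#' Thin driver over [make_calibration_dataset()] for the command line:
#' validates the configuration before any I/O, writes the dataset and a
#' run log.
#'
#' @param preset preset name (see [preset_config()]).
#' @param out_dir output directory.
#' @param seed master seed.
#' @param ... overrides passed to [generator_config()].
#' @return the dataset list, invisibly.
#' @export
run_simulate <- function(preset = "mef28", out_dir, seed = 1, ...) {
  gcfg <- preset_config(preset, seed = seed, ...)
  ds <- make_calibration_dataset(gcfg, dir = out_dir)
  log_lines(file.path(out_dir, "run.log"),
            sprintf("simulate preset=%s seed=%d spectra=%d", preset, seed,
                    length(ds$spectra)))
  invisible(ds)
}

log_lines <- function(path, lines) {
  con <- file(path, "a")
  on.exit(close(con))
  writeLines(paste(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), lines), con)
}

read_dataset_spectra <- function(manifest, base_dir) {
  lapply(seq_len(nrow(manifest)), function(i)
    read_spectrum(file.path(base_dir, manifest$file[i]),
                  sample_id = manifest$sample_id[i],
                  replicate = manifest$replicate[i]))
}

#' Run the full calibration workflow
#'
#' The five-step protocol driver: preprocess the calibration spectra,
#' apply the intensity-threshold filter, select the informative-peak
#' panel, cross-validate both calibrators (PLS baseline and ANN) by
#' leave-one-out, and train the final models on the full dataset.
#'
#' @param dataset either a list with `spectra` and `manifest` (e.g. from
#'   [make_calibration_dataset()]) or the path of a manifest CSV whose
#'   `file` column points at the spectra.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for result files: `summary.json`
#'   (Table-1-shaped metrics for both calibrators), `panel.csv`,
#'   `predictions_ann.csv` / `predictions_pls.csv`, `ann_model.json`,
#'   `reference.csv`, `config.yaml`, `run.log`.
#' @return an object of class `mix_calibration`: the thresholded matrix,
#'   panel, LOO [calibration_result()]s (`$ann`, `$pls`), final trained
#'   models, alignment reference and configuration.
#' @export
run_calibrate <- function(dataset, config = pipeline_config(),
                          out_dir = NULL) {
  config <- validate_config(config)
  if (is.character(dataset)) {
    manifest <- read_manifest(dataset)
    spectra <- read_dataset_spectra(manifest, dirname(dataset))
  } else {
    manifest <- dataset$manifest
    spectra <- dataset$spectra
  }
  grid <- mz_grid(config$grid_lo, config$grid_hi, config$grid_bins)
  pp <- preprocess_spectra(spectra, manifest, grid = grid,
                           max_shift_bins = config$max_shift_bins,
                           half_window_bins = config$half_window_bins,
                           window_bins = config$window_bins,
                           polyorder = config$polyorder,
                           normalize_mode = config$normalize_mode)
  thr <- threshold_filter(pp$matrix, threshold = config$threshold)
  y <- manifest$n_cells_B
  panel <- select_panel(thr, y, target_size = min(config$panel_size,
                                                  ncol(thr$values)),
                        seed = config$seed, cv_folds = config$cv_folds,
                        n_components = config$spls_components,
                        sparsity = config$sparsity)
  Xsel <- apply_panel(thr, panel)
  loo_pls <- loo_cross_validate(Xsel, y, method = "pls",
                                n_components = config$pls_components)
  loo_ann <- loo_cross_validate(Xsel, y, method = "ann", seed = config$seed,
                                n_hidden = config$n_hidden,
                                epochs = config$epochs,
                                learning_rate = config$learning_rate,
                                momentum = config$momentum)
  final_pls <- pls_calibrator(Xsel, y,
                              n_components = min(config$pls_components,
                                                 nrow(Xsel$values) - 1L,
                                                 ncol(Xsel$values)))
  final_ann <- ann_calibrator(Xsel, y, n_hidden = config$n_hidden,
                              epochs = config$epochs,
                              learning_rate = config$learning_rate,
                              momentum = config$momentum,
                              seed = config$seed)
  obj <- structure(list(matrix = thr, panel = panel, X = Xsel, y = y,
                        manifest = manifest, pls = loo_pls, ann = loo_ann,
                        final_pls = final_pls, final_ann = final_ann,
                        reference = pp$reference, offsets = pp$offsets,
                        grid = grid, total = max(manifest$n_cells_A +
                                                 manifest$n_cells_B),
                        config = config),
                   class = "mix_calibration")
  if (!is.null(out_dir)) write_calibration_run(obj, out_dir)
  obj
}

summary_table <- function(obj) {
  list(PLS = list(RMS = obj$pls$rms, k = obj$pls$k, R2 = obj$pls$r2),
       ANN = list(RMS = obj$ann$rms, k = obj$ann$k, R2 = obj$ann$r2))
}

write_calibration_run <- function(obj, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(summary_table(obj), file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  panel_out <- data.frame(mz = obj$panel$mz, rank = seq_len(nrow(obj$panel)),
                          sd_score = obj$panel$sd_score,
                          chosen_by = obj$panel$chosen_by)
  utils::write.csv(panel_out, file.path(out_dir, "panel.csv"),
                   row.names = FALSE)
  write_calibration_result(obj$ann,
                           csv_path = file.path(out_dir, "predictions_ann.csv"))
  write_calibration_result(obj$pls,
                           csv_path = file.path(out_dir, "predictions_pls.csv"))
  write_ann_model(obj$final_ann, file.path(out_dir, "ann_model.json"))
  ref <- data.frame(mz = grid_centers(obj$grid), intensity = obj$reference)
  utils::write.csv(ref, file.path(out_dir, "reference.csv"), row.names = FALSE)
  yaml::write_yaml(unclass(obj$config), file.path(out_dir, "config.yaml"))
  log_lines(file.path(out_dir, "run.log"),
            sprintf("calibrate n=%d panel=%d ann_rms=%.6g pls_rms=%.6g seed=%d",
                    length(obj$y), nrow(obj$panel), obj$ann$rms, obj$pls$rms,
                    obj$config$seed))
  invisible(out_dir)
}

#' @export
#' @method print mix_calibration
print.mix_calibration <- function(x, ...) {
  cat(sprintf("<mix_calibration> %d spectra, panel of %d peaks\n",
              length(x$y), nrow(x$panel)))
  cat(sprintf("  PLS LOO: RMS %.4g cells, k %.3f, R2 %.4f\n",
              x$pls$rms, x$pls$k, x$pls$r2))
  cat(sprintf("  ANN LOO: RMS %.4g cells, k %.3f, R2 %.4f\n",
              x$ann$rms, x$ann$k, x$ann$r2))
  invisible(x)
}

#' @export
#' @method summary mix_calibration
summary.mix_calibration <- function(object, ...) {
  print(object)
  cat("\nPanel m/z:", paste(sprintf("%.1f", sort(object$panel$mz)),
                            collapse = ", "), "\n")
  cat(sprintf("ANN runs-test p: %.3g; PLS runs-test p: %.3g\n",
              object$ann$runs_p, object$pls$runs_p))
  invisible(object)
}

#' Predict contamination in new spectra
#'
#' Applies a fitted calibration run to unknown samples: the spectra are
#' preprocessed with the stored grid, alignment reference and chain
#' parameters, the panel columns are extracted, and the trained ANN
#' predicts the contaminant cell count (also reported as percent of the
#' declared total).
#'
#' @param object a `mix_calibration` from [run_calibrate()].
#' @param newdata list of raw [spectrum()]s, or a character vector of
#'   spectrum file paths.
#' @param calibrator `"ann"` (default) or `"pls"`.
#' @param ... unused.
#' @return data.frame with `sample_id`, `replicate`, `predicted_cells`,
#'   `predicted_percent`.
#' @export
#' @method predict mix_calibration
predict.mix_calibration <- function(object, newdata,
                                    calibrator = c("ann", "pls"), ...) {
  calibrator <- match.arg(calibrator)
  if (is.character(newdata))
    newdata <- lapply(newdata, read_spectrum)
  if (inherits(newdata, "spectrum")) newdata <- list(newdata)
  cfg <- object$config
  man <- data.frame(sample_id = vapply(newdata, `[[`, "", "sample_id"),
                    file = NA_character_,
                    n_cells_A = 0, n_cells_B = 0,
                    replicate = vapply(newdata, `[[`, 1L, "replicate"))
  key <- paste(man$sample_id, man$replicate)
  if (anyDuplicated(key)) {          # tolerate unnamed ad-hoc inputs
    man$sample_id <- sprintf("unknown%03d", seq_len(nrow(man)))
    man$replicate <- 1L
    for (i in seq_along(newdata)) {
      newdata[[i]]$sample_id <- man$sample_id[i]
      newdata[[i]]$replicate <- 1L
    }
  }
  class(man) <- c("sample_manifest", "data.frame")
  pp <- preprocess_spectra(newdata, man, grid = object$grid,
                           max_shift_bins = cfg$max_shift_bins,
                           half_window_bins = cfg$half_window_bins,
                           window_bins = cfg$window_bins,
                           polyorder = cfg$polyorder,
                           normalize_mode = cfg$normalize_mode,
                           reference = object$reference)
  Xnew <- apply_panel(pp$matrix, object$panel)
  pred <- if (calibrator == "ann") ann_predict(object$final_ann, Xnew)
          else predict(object$final_pls, Xnew)
  data.frame(sample_id = man$sample_id, replicate = man$replicate,
             predicted_cells = pred,
             predicted_percent = 100 * pred / object$total)
}

#' @rdname predict.mix_calibration
#' @param calibration a `mix_calibration`.
#' @param spectra_paths character vector of spectrum files.
#' @param out_csv optional CSV path for the predictions.
#' @export
run_predict <- function(calibration, spectra_paths, out_csv = NULL,
                        calibrator = "ann") {
  out <- predict(calibration, spectra_paths, calibrator = calibrator)
  if (!is.null(out_csv))
    utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
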