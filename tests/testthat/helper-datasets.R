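# Shared fixtures, built once per test run.

# A coarse grid keeps unit tests fast; synthetic peaks (sigma >= 2 Da) are
# still resolved at 2 Da bins.
small_grid <- function() mz_grid(2000, 20000, 9001)

# Small default-noise calibration set: 10 mixtures + pures, 2 replicates.
.fixture <- new.env(parent = emptyenv())

small_default_dataset <- function() {
  if (is.null(.fixture$ds)) {
    f <- c(0.02, 0.05, 0.1, 0.2, 0.3, 0.45, 0.6, 0.75, 0.9, 0.97)
    n_b <- round(c(0, f, 1) * 1e6)
    cfg <- generator_config(seed = 42)
    cfg$designs <- data.frame(n_cells_A = 1e6 - n_b, n_cells_B = n_b)
    cfg$replicates <- 2L
    .fixture$ds <- make_calibration_dataset(cfg)
  }
  .fixture$ds
}

# The same dataset pushed through the chain on the coarse grid, with the
# baseline/alignment windows rescaled to the 2 Da bin width.
small_default_pipeline <- function() {
  if (is.null(.fixture$pipe)) {
    ds <- small_default_dataset()
    pp <- preprocess_spectra(ds$spectra, ds$manifest, grid = small_grid(),
                             max_shift_bins = 15, half_window_bins = 75)
    thr <- threshold_filter(pp$matrix)
    y <- ds$manifest$n_cells_B
    panel <- select_panel(thr, y, target_size = 10, seed = 1)
    .fixture$pipe <- list(ds = ds, pp = pp, thr = thr, y = y, panel = panel,
                          X = apply_panel(thr, panel))
  }
  .fixture$pipe
}

# A spectrum sampled exactly at the centers of a grid.
grid_spectrum <- function(grid, intensity, ...) {
  spectrum(grid_centers(grid), intensity, ...)
}

random_intensity_matrix <- function(m, n, stage = "thresholded") {
  intensity_matrix(matrix(abs(rnorm(m * n)), m, n),
                   row_ids = paste0("r", seq_len(m)),
                   col_mz = sort(runif(n, 2000, 20000)), stage = stage)
}

# Full mef28 preset (seed 1) pushed through the default-grid pipeline;
# shared by the heavier end-to-end checks.
mef28_pipeline <- function() {
  if (is.null(.fixture$mef28)) {
    ds <- make_calibration_dataset(preset_config("mef28", seed = 1))
    pp <- preprocess_spectra(ds$spectra, ds$manifest)
    thr <- threshold_filter(pp$matrix)
    y <- ds$manifest$n_cells_B
    panel <- select_panel(thr, y, target_size = 10, seed = 1)
    .fixture$mef28 <- list(ds = ds, thr = thr, y = y, panel = panel,
                           X = apply_panel(thr, panel))
  }
  .fixture$mef28
}
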