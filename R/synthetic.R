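#' Generator configuration for synthetic two-component fingerprints
#'
#' The generator emulates intact-cell MALDI-TOF fingerprints of two cell
#' types (A = host, B = contaminant) that share most peak locations but
#' each carry a few unique marker peaks; component B's first two markers
#' sit at m/z 3992 and 9908.  Peak amplitudes follow a nonlinear response
#' emulating "MALDI effects": each component's contribution is damped by
#' cross-component ionization suppression `1 / (1 + s * c_other)` and the
#' summed abundance `u` is passed through the saturating response
#' `r(u) = u^gamma / (1 + K * u^gamma)` (`gamma = 1`, `s = 0`, `K = 0`
#' is the exactly linear limit).  Replicate-level distortions are a
#' global m/z jitter, an exponentially decaying baseline, per-peak
#' multiplicative noise and additive point noise.
#'
#' @param n_peaks peaks per component (shared + unique; default 60, of
#'   which 5 per component are unique markers).
#' @param n_unique unique marker peaks per component (>= 2).
#' @param designs data.frame with columns `n_cells_A`, `n_cells_B`; one
#'   row per calibration mixture.  Defaults to `NULL` (set by presets).
#' @param total declared total cell count per sample (default 1e6).
#' @param replicates technical replicates per mixture (default 5,
#'   emulating pentaplicate spotting).
#' @param gamma saturation exponent of the response (default 0.6;
#'   1 = linear).
#' @param sat_K saturation strength K of the response denominator
#'   (default 2; 0 disables saturation).
#' @param suppression cross-suppression strength s per cell (default
#'   5e-7; at 1e6 foreign cells the contribution is damped by 1/1.5).
#' @param jitter_sd SD of the global per-replicate m/z shift (Da).
#' @param baseline_amp amplitude of the exponentially decaying baseline,
#'   relative to the unit per-cell intensity scale.
#' @param mult_cv coefficient of variation of the per-peak multiplicative
#'   (lognormal) noise.
#' @param additive_sd SD of the additive point noise.
#' @param seed integer master seed; every random draw derives from it.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_peaks = 60, n_unique = 5, designs = NULL,
                             total = 1e6, replicates = 5, gamma = 0.6,
                             sat_K = 2, suppression = 5e-7, jitter_sd = 0.4,
                             baseline_amp = 0.05, mult_cv = 0.012,
                             additive_sd = 0.001, seed = 1) {
  stopifnot(n_peaks >= 10, n_unique >= 2, replicates >= 1,
            gamma > 0, sat_K >= 0, suppression >= 0, jitter_sd >= 0,
            baseline_amp >= 0, mult_cv >= 0, additive_sd >= 0)
  structure(list(n_peaks = n_peaks, n_unique = n_unique, designs = designs,
                 total = total, replicates = as.integer(replicates),
                 gamma = gamma, sat_K = sat_K, suppression = suppression,
                 jitter_sd = jitter_sd, baseline_amp = baseline_amp,
                 mult_cv = mult_cv, additive_sd = additive_sd,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Noise-free linear variant of a generator configuration
#'
#' Convenience for closed-form checks: sets `gamma = 1`, `sat_K = 0`,
#' `suppression = 0` and all jitter/baseline/noise terms to 0, so peak
#' amplitudes are exactly proportional to the mixing composition.
#'
#' @param config a [generator_config()].
#' @return the modified configuration.
#' @export
linear_config <- function(config = generator_config()) {
  config$gamma <- 1
  config$sat_K <- 0
  config$suppression <- 0
  config$jitter_sd <- 0
  config$baseline_amp <- 0
  config$mult_cv <- 0
  config$additive_sd <- 0
  config
}

# minimum spacing between generated peak locations (Da): peaks stay fully
# resolved after smoothing (6 sigma + filter width < spacing); also
# guarantees the >= 20 Da marker-to-shared-peak separation
.PEAK_MIN_SPACING <- 120

#' Generate the two component peak profiles
#'
#' Seeded construction of the A and B peak lists: shared locations with
#' independent per-cell intensities in each component, plus `n_unique`
#' unique markers each (disjoint between components, separated from all
#' other peaks by at least 120 Da; B's first two markers at m/z 3992 and
#' 9908).  Per-cell total ion yield is equalized between the components.
#'
#' @param config a [generator_config()].
#' @return list with elements `A` and `B`, each a data.frame with columns
#'   `mz`, `intensity` (per-cell yield, arbitrary units), `width`
#'   (Gaussian SD, Da) and `marker` (logical).
#' @export
make_component_profiles <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n_unique <- config$n_unique
  n_shared <- config$n_peaks - n_unique
  if (n_shared < 1 || n_shared / config$n_peaks < 0.7)
    stop("infeasible profile: shared fraction below 0.7", call. = FALSE)
  n_total <- n_shared + 2L * n_unique
  lo <- 2100; hi <- 19500
  if (n_total * .PEAK_MIN_SPACING > (hi - lo))
    stop("infeasible profile: too many peaks for the m/z range", call. = FALSE)
  set.seed(config$seed)
  locs <- c(3992, 9908)                       # B's designated markers
  tries <- 0L
  while (length(locs) < n_total) {
    cand <- stats::runif(1, lo, hi)
    if (min(abs(cand - locs)) >= .PEAK_MIN_SPACING) locs <- c(locs, cand)
    tries <- tries + 1L
    if (tries > 100000L)
      stop("infeasible profile: could not place peaks", call. = FALSE)
  }
  b_marker_mz <- locs[seq_len(n_unique)]             # starts at 3992, 9908
  a_marker_mz <- locs[n_unique + seq_len(n_unique)]
  shared_mz <- locs[(2L * n_unique + 1L):n_total]
  width_of <- function(mz) stats::runif(length(mz), 3, 7)
  all_mz <- c(shared_mz, a_marker_mz, b_marker_mz)
  all_w <- width_of(all_mz)                  # one width per location
  w_shared <- all_w[seq_along(shared_mz)]
  w_a <- all_w[length(shared_mz) + seq_along(a_marker_mz)]
  w_b <- all_w[length(shared_mz) + length(a_marker_mz) + seq_along(b_marker_mz)]
  # heavy-tailed per-cell yields: a few dominant peaks over many small
  # ones, as in real intact-cell fingerprints
  ln <- function(n, lo) pmax(stats::rlnorm(n, log(0.3), 1.5), lo)
  i_shared_A <- ln(n_shared, 0.05)
  i_shared_B <- ln(n_shared, 0.05)
  i_a <- ln(n_unique, 0.3)
  i_b <- ln(n_unique, 0.3)
  A <- data.frame(mz = c(shared_mz, a_marker_mz),
                  intensity = c(i_shared_A, i_a),
                  width = c(w_shared, w_a),
                  marker = c(rep(FALSE, n_shared), rep(TRUE, n_unique)))
  B <- data.frame(mz = c(shared_mz, b_marker_mz),
                  intensity = c(i_shared_B, i_b),
                  width = c(w_shared, w_b),
                  marker = c(rep(FALSE, n_shared), rep(TRUE, n_unique)))
  # equal per-cell total ion yield (Gaussian area = amplitude x width) so
  # the sum-normalized fingerprint is exactly affine in the linear limit
  B$intensity <- B$intensity *
    sum(A$intensity * A$width) / sum(B$intensity * B$width)
  A <- A[order(A$mz), ]; rownames(A) <- NULL
  B <- B[order(B$mz), ]; rownames(B) <- NULL
  list(A = A, B = B)
}

# noiseless per-peak amplitudes for a composition, over the union peak list
peak_amplitudes <- function(profiles, n_cells_A, n_cells_B, config) {
  mz <- sort(unique(c(profiles$A$mz, profiles$B$mz)))
  ia <- profiles$A$intensity[match(mz, profiles$A$mz)]
  ib <- profiles$B$intensity[match(mz, profiles$B$mz)]
  ia[is.na(ia)] <- 0; ib[is.na(ib)] <- 0
  wa <- profiles$A$width[match(mz, profiles$A$mz)]
  wb <- profiles$B$width[match(mz, profiles$B$mz)]
  width <- ifelse(is.na(wa), wb, wa)
  s <- config$suppression
  u <- (n_cells_A * ia / (1 + s * n_cells_B) +
        n_cells_B * ib / (1 + s * n_cells_A)) / config$total
  r <- ifelse(u > 0, u^config$gamma / (1 + config$sat_K * u^config$gamma), 0)
  data.frame(mz = mz, amplitude = r, width = width)
}

#' Render one raw mixture spectrum
#'
#' Evaluates the union peak list at the given composition through the
#' suppression + saturation response, renders each peak as a Gaussian on
#' an irregular fine m/z axis (mean spacing 0.5 Da), and adds the
#' replicate-level distortions (global m/z jitter, decaying baseline,
#' per-peak multiplicative noise, additive point noise).  Fully
#' determined by `replicate_seed`.
#'
#' @param profiles output of [make_component_profiles()].
#' @param design numeric `c(n_cells_A, n_cells_B)`; must sum to
#'   `config$total`.
#' @param config a [generator_config()].
#' @param replicate_seed integer seed for this replicate's draws.
#' @param sample_id,replicate metadata for the returned spectrum.
#' @return a raw [spectrum()] on an irregular axis.
#' @export
render_mixture_spectrum <- function(profiles, design, config,
                                    replicate_seed = 1L,
                                    sample_id = NA_character_,
                                    replicate = 1L) {
  stopifnot(length(design) == 2L)
  if (sum(design) != config$total)
    stop("design total does not match config total", call. = FALSE)
  # the instrument's sampling raster: irregular but fixed per dataset
  # (drawn from the master seed); per-replicate variation enters through
  # the jitter/noise terms below
  set.seed(config$seed + 2L)
  n_est <- ceiling((20000 - 2000) / 0.5) + 100L
  steps <- stats::runif(n_est, 0.35, 0.65)
  axis <- 2000 + cumsum(c(0, steps))
  axis <- axis[axis <= 20000]
  set.seed(replicate_seed)
  shift <- if (config$jitter_sd > 0) stats::rnorm(1, 0, config$jitter_sd) else 0
  pk <- peak_amplitudes(profiles, design[1L], design[2L], config)
  fac <- if (config$mult_cv > 0)
    exp(stats::rnorm(nrow(pk), 0, config$mult_cv)) else rep(1, nrow(pk))
  y <- numeric(length(axis))
  for (k in seq_len(nrow(pk))) {
    a <- pk$amplitude[k] * fac[k]
    if (a <= 0) next
    ctr <- pk$mz[k] + shift
    w <- pk$width[k]
    idx <- which(axis > ctr - 6 * w & axis < ctr + 6 * w)
    if (length(idx))
      y[idx] <- y[idx] + a * exp(-(axis[idx] - ctr)^2 / (2 * w^2))
  }
  if (config$baseline_amp > 0)
    y <- y + config$baseline_amp * exp(-(axis - 2000) / 4000)
  if (config$additive_sd > 0)
    y <- y + stats::rnorm(length(axis), 0, config$additive_sd)
  spectrum(axis, pmax(y, 0), sample_id = sample_id, replicate = replicate)
}

#' Preset generator configurations
#'
#' Three calibration-series presets:
#' \describe{
#'   \item{mef28}{28 defined mixtures plus the two pure populations,
#'     total 1e6 cells, 5 replicates (150 spectra).}
#'   \item{mesc34}{34 mixtures plus pures, total 0.5e6 cells,
#'     5 replicates (180 spectra).}
#'   \item{valid50}{50 independent single-replicate mixtures with random
#'     compositions, total 1e6 cells (50 spectra), for external
#'     validation of a trained calibrator.}
#' }
#'
#' @param name preset name.
#' @param seed master seed.
#' @param ... further arguments passed to [generator_config()]
#'   (noise/nonlinearity overrides).
#' @return a [generator_config()] with `designs`, `total` and
#'   `replicates` filled in.
#' @export
preset_config <- function(name = c("mef28", "mesc34", "valid50"), seed = 1,
                          ...) {
  name <- match.arg(name)
  if (name == "mef28") {
    f <- c(0.01, 0.02, 0.03, 0.05, 0.07, 0.10, 0.13, 0.16, 0.20, 0.24,
           0.28, 0.32, 0.36, 0.40, 0.44, 0.48, 0.52, 0.56, 0.60, 0.64,
           0.68, 0.72, 0.76, 0.80, 0.85, 0.90, 0.95, 0.97)
    total <- 1e6
    f <- c(0, f, 1)                          # plus the two pure populations
    reps <- 5
  } else if (name == "mesc34") {
    f <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06, 0.08, 0.10, 0.12, 0.15,
           0.18, 0.21, 0.24, 0.27, 0.30, 0.33, 0.36, 0.39, 0.42, 0.45,
           0.48, 0.52, 0.56, 0.60, 0.64, 0.68, 0.72, 0.76, 0.80, 0.84,
           0.88, 0.92, 0.95, 0.97)
    total <- 0.5e6
    f <- c(0, f, 1)
    reps <- 5
  } else {
    set.seed(as.integer(seed) + 977L)
    f <- sort(stats::runif(50, 0.005, 0.97))
    total <- 1e6
    reps <- 1
  }
  n_b <- round(f * total)
  designs <- data.frame(n_cells_A = total - n_b, n_cells_B = n_b)
  generator_config(designs = designs, total = total, replicates = reps,
                   seed = seed, ...)
}

#' Generate a full synthetic calibration dataset
#'
#' Builds the component profiles, renders every (mixture, replicate)
#' spectrum with its own derived seed, and assembles the manifest and
#' ground truth.  Optionally writes everything to disk (TSV spectra,
#' CSV manifest, CSV ground truth, JSON config snapshot).
#'
#' @param config a [generator_config()] with `designs` set (see
#'   [preset_config()]).
#' @param dir optional output directory; created if missing.
#' @return list with `spectra` (list of raw [spectrum()]s), `manifest`
#'   (a `sample_manifest`), `truth` (data.frame of compositions),
#'   `profiles` and `config`.
#' @export
make_calibration_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(config$designs))
    stop("config$designs is not set; use preset_config() or supply designs",
         call. = FALSE)
  profiles <- make_component_profiles(config)
  d <- config$designs
  n_mix <- nrow(d)
  n_spec <- n_mix * config$replicates
  set.seed(config$seed + 1L)
  seeds <- sample.int(2147480000L, n_spec)
  ids <- sprintf("s%03d", seq_len(n_mix))
  spectra <- vector("list", n_spec)
  man <- data.frame(sample_id = rep(ids, each = config$replicates),
                    file = NA_character_,
                    n_cells_A = rep(d$n_cells_A, each = config$replicates),
                    n_cells_B = rep(d$n_cells_B, each = config$replicates),
                    replicate = rep(seq_len(config$replicates), times = n_mix),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n_spec)) {
    spectra[[i]] <- render_mixture_spectrum(
      profiles, c(man$n_cells_A[i], man$n_cells_B[i]), config,
      replicate_seed = seeds[i], sample_id = man$sample_id[i],
      replicate = man$replicate[i])
  }
  if (!is.null(dir)) {
    sp_dir <- file.path(dir, "spectra")
    dir.create(sp_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_spec)) {
      fn <- file.path("spectra", sprintf("%s_r%d.tsv", man$sample_id[i],
                                         man$replicate[i]))
      write_spectrum(spectra[[i]], file.path(dir, fn), format = "tsv")
      man$file[i] <- fn
    }
  }
  manifest <- validate_manifest(man, total = config$total)
  truth <- man[, c("sample_id", "replicate", "n_cells_A", "n_cells_B")]
  if (!is.null(dir)) {
    write_manifest(manifest, file.path(dir, "manifest.csv"))
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
    jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(spectra = spectra, manifest = manifest, truth = truth,
       profiles = profiles, config = config)
}
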