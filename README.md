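# maldimix

Quantifies cross-contamination in two-component cell mixtures from
intact-cell MALDI-TOF mass-spectral fingerprints by multivariate
calibration.

## The problem and the method

A culture of a host cell line (A) contaminated by a second cell type
(B) yields a whole-cell MALDI-TOF fingerprint — dozens of unidentified
peaks in the 2000–20000 m/z range — that encodes the mixture's
composition.  Because the two types share most peaks and peak intensity
responds nonlinearly to analyte abundance ("MALDI effects": ionization
suppression/enhancement, saturation), single marker peaks quantify
poorly.  maldimix instead calibrates on mixtures of known composition
(n_A + n_B cells summing to a fixed total, spotted in technical
pentaplicates):

1. **Preprocessing** of each spectrum: resampling to a common 30000-bin
   m/z grid, alignment to the median reference, rolling-minimum
   baseline subtraction, Savitzky–Golay smoothing, and normalization to
   unit sum (ΣXᵢ = 1); then an intensity-threshold filter keeps only
   m/z columns whose maximum exceeds 1×10⁻³.
2. **Informative-peak selection** by three methods — normalized
   standard deviations (SD of each column ÷ pooled SD), Lasso, and
   sparse PLS — merged into a fixed-size panel (10 or 30 peaks).
3. **Calibration**: a NIPALS PLS1 baseline and a back-propagation
   neural network (panel inputs → 4 logistic-sigmoid hidden neurons →
   1 sigmoid output, min-max scaling to [0.1, 0.9], online gradient
   descent with momentum) both map the selected fingerprint to the
   contaminant **cell count**.
4. **Validation** by leave-one-out cross-validation, scored with the
   root-mean-square residual over N spectra and M outputs,

   RMS = √( Σₚ Σₖ (o_pk − o*_pk)² / (N·M) ),

   the slope k and R² of the OLS line of predicted vs experimental
   counts, and a runs test for residual randomness.  PCA diagnostics
   (scores, loadings, scree) verify that pure populations and mixtures
   separate.

A seeded synthetic-fingerprint generator (shared + marker peaks at
m/z 3992/9908, saturating response with cross-suppression, jitter,
baseline, noise, pentaplicate structure) defines reproducible study
conditions, so the entire pipeline is testable without instrument data.

## Worked example

```r
library(maldimix)

# 34 defined mixtures + pure populations, total 0.5e6 cells,
# pentaplicates -> 180 synthetic spectra with known ground truth
ds  <- make_calibration_dataset(preset_config("mesc34", seed = 1))

pp  <- preprocess_spectra(ds$spectra, ds$manifest)    # 180 x 30000
thr <- threshold_filter(pp$matrix)                    # 180 x 90
y   <- ds$manifest$n_cells_B
panel <- select_panel(thr, y, target_size = 30, seed = 1)
X   <- apply_panel(thr, panel)

loo_cross_validate(X, y, method = "pls")
#> <calibration_result> pls-loo: n = 180, RMS = 2.544e+04 cells, k = 0.9788, R2 = 0.9750
loo_cross_validate(X, y, method = "ann", epochs = 3000, seed = 1)
#> <calibration_result> ann-loo: n = 180, RMS = 4860 cells, k = 0.9994, R2 = 0.9991
```

The linear PLS baseline is limited by the generator's MALDI-effect
nonlinearity (RMS ≈ 2.5×10⁴ of a 5×10⁵-cell total, ~5%), while the
leave-one-out network calibrates every left-out spectrum to ≈4.9×10³
cells (~1%) with slope ≈1 and R² ≈ 0.999 — the nonlinear calibrator
beats the linear baseline by ~5×.  `run_calibrate()` wraps these stages
(plus final model fits and file outputs) into one call, and
`predict()` on its result quantifies contamination in new spectra;
`inst/exec/maldimix.R` exposes simulate/calibrate/predict as shell
subcommands.

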