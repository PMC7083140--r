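# myoslice

Structure-function analysis of failing human myocardium studied in
living tissue slices. The package quantifies **cardiomyocyte t-system
remodeling** from 3D membrane-stained confocal stacks, extracts **twitch
kinetics and the force-frequency relationship (FFR)** from paced force
recordings, measures **myocyte orientation disarray and sarcomere
length** in 2D tile scans, and relates structure, Ca²⁺-handling protein
expression and contractile function through the study's regression
models. It is written for cardiac physiologists and image analysts who
work with myocardial slice preparations.

Because the underlying patient data are not publicly deposited, a
first-class synthetic-data module (`gen_tsystem_stack()`,
`gen_myocyte_mosaic()`, `gen_sarcomere_pattern()`, `gen_force_trace()`,
`gen_cohort()`) produces every input modality with exact ground truth;
all tests run against these generators.

## The quantities at the core

* **ΔTT** — the mean intracellular distance to the closest t-tubule:
  a 3D anisotropy-aware Euclidean distance transform of the segmented
  t-tubule mask, averaged over the cardiomyocyte mask (µm). Larger ΔTT
  means more t-system loss.
* **Twitch parameters** — per contraction: peak active force F_max, time
  to peak TTP, time to relaxation TTR (peak → 90 % decay), 90 %
  contraction duration CD90 = TTP + TTR; averaged over the last 30 s of
  each 120 s pacing interval (0.2 / 0.5 / 1 / 2 Hz staircase).
* **FFR ratios** — F₁Hz/F₀.₅Hz and F₂Hz/F₀.₅Hz (> 1: positive FFR).
  Wall tension T = F/A with A = 5 mm × 0.25 mm = 1.25 mm².
* **Interaction model** — the no-intercept fit
  TTR = b₁·ΔTT + b₂·(NCX1·ΔTT), reported in the factored form
  TTR = b₁·(ΔTT − r·NCX1·ΔTT), r = −b₂/b₁, and compared against the
  ΔTT-only model by a likelihood-ratio test
  (statistic n·ln(RSS₀/RSS₁), χ² reference).
* **Morphometry** — iterative watershed segmentation of WGA tile scans,
  per-cell orientation from 2nd-order image moments, axial dispersion and
  the fraction of myocytes deviating > 30° from the main fiber
  orientation; sarcomere length from the band-limited (1/2.5–1/1.5 µm⁻¹)
  2D power spectrum.

## Worked example

Segment a noisy synthetic membrane stack and recover its ΔTT:

```r
library(myoslice)

ph <- gen_tsystem_stack(tubule_phantom_spec(
  cell_extent_um = c(5.8, 5.8, 5.8), geometry = "full-lattice",
  lattice_spacing_um = 1.6, tubule_radius_um = 0.15, noise_sd = 2,
  attenuation_coefficient_per_um = 0.01, blur_sigma_um = 0.1,
  rng_seed = 16))
metrics <- analyze_tsystem_stack(ph$stack, psf_sigma_um = 0.1,
                                 iterations = 10, surface_margin_um = 0.3)
metrics
#> tsystem_metrics: dTT = 0.4548 um over 1 stack(s)
ph$truth$true_delta_tt_um
#> [1] 0.4518
```

The estimated ΔTT (0.455 µm) recovers the phantom's exhaustively
computed truth (0.452 µm) to within 1 %. Analyze a paced force trace
with a negative FFR and fit the interaction model on a synthetic cohort:

```r
gen <- gen_force_trace(amplitude_mN = c(`0.2` = 0.9, `0.5` = 1,
                                        `1` = 0.86, `2` = 0.78),
                       noise_sd = 0.002, rng_seed = 2)
fr <- interval_average(gen$trace, geometry = slice_geometry())
unlist(ffr_ratios(fr))
#> ffr_1_0p5 ffr_2_0p5
#> 0.8592711 0.7782687

co <- gen_cohort(n_samples = 13, rng_seed = 42)
fit <- interaction_fit(co$samples$delta_tt_um, co$samples$ncx1,
                       co$samples$ttr_s)
fit
#> regression_fit (n = 13): R2 = 1.000 (uncentered (no-intercept convention)), F = 6.34e+04, p = 4.57e-23
#>   term    estimate           se
#>    dtt  0.36036848 0.0018736429
#>  inter -0.02510616 0.0009726702
red <- interaction_fit(co$samples$delta_tt_um, rep(0, 13), co$samples$ttr_s)
likelihood_ratio_test(fit, red)$p_value
#> [1] 2.51e-13
```

Both programmed FFR ratios (0.86, 0.78) come back within 0.5 %, and the
fitted leading coefficient (0.360) and interaction ratio
(−(−0.0251)/0.360 = 0.0697) recover the cohort generator's coefficients
(0.36, 0.069). `run_pipeline(run_config(rng_seed = 1))` chains all four
stages — imaging, morphometry, kinetics, statistics — into one
deterministic report.

## Package layout

* `R/synth-*.R` — synthetic-data generators with ground truth
* `R/tsystem.R`, `src/distance.cpp` — imaging chain and the exact 3D
  distance transform (Rcpp)
* `R/morphometry.R` — watershed, orientations, sarcomere length
* `R/kinetics.R` — twitch parameters, FFR, wall tension
* `R/stats_models.R` — fits, LRT, group tests, Holm, densitometry
* `R/pipeline.R`, `R/io.R` — orchestration and TIFF/CSV/JSON formats
* `vignettes/myoslice-methods.Rmd` — the methods vignette (models,
  parameter choices, limitations)
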