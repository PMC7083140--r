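---
title: "Methods: quantifying t-system remodeling, twitch kinetics and their statistical coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying t-system remodeling, twitch kinetics and their statistical coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`myoslice` implements the quantitative core of a structure-function
analysis of failing human myocardium studied in living tissue slices:

1. **t-system remodeling** from 3D membrane-stained (WGA) confocal
   stacks, summarized as ΔTT, the mean intracellular distance to the
   nearest t-tubule;
2. **twitch kinetics and the force-frequency relationship (FFR)** from
   force recordings of slices paced through a 0.2/0.5/1/2 Hz staircase;
3. **myocyte morphometry** (orientation disarray, sarcomere length) from
   2D tile scans;
4. **the statistical layer** linking ΔTT, Ca²⁺-handling protein
   expression and contractile function, including a no-intercept
   interaction model of relaxation time and its likelihood-ratio test.

Because the underlying patient data are not publicly deposited, the
package ships a first-class synthetic-data module that generates every
input modality with exact ground truth. All tests and the acceptance
script run against these generators.

# The ΔTT metric

## Model

A cardiomyocyte's t-system is a network of membrane invaginations that
carries the action potential into the cell interior. Its loss in heart
failure increases the distance that Ca²⁺-release triggering must cover.
ΔTT quantifies this: for every voxel of the cell mask, the Euclidean
distance to the nearest t-tubule voxel is computed with a 3D distance
transform, and ΔTT is the mean over the cell.

The distance transform is the exact separable lower-envelope (parabola)
algorithm, applied per axis with the physical voxel pitch, so anisotropic
voxels are handled without resampling. Tubule voxels themselves
contribute distance 0 and are part of the average by default
(`include_tubule_voxels = TRUE`); excluding them is a documented switch.
The average over distance-0 voxels matches the reading of ΔTT as a mean
over the whole intracellular space; on realistic tubule densities the
difference between the two conventions is below the discretization
error.

An independent oracle, `brute_force_dtt()`, computes the same quantity by
exhaustive all-pairs search; `compute_dtt()` must (and does) agree with
it to machine precision, since both are exact.

## Image-processing chain

The chain mirrors standard confocal practice:

* **Attenuation correction** fits plane-mean intensity against depth on a
  log scale and divides out the exponential gain. This is the simplest
  model consistent with depth-dependent signal loss; the estimated
  coefficient is attached to the result.
* **Filtering/deconvolution** is Richardson-Lucy with a Gaussian PSF
  (default sigma 0.3 µm axial / 0.15 µm lateral, 10 iterations), with an
  optional Gaussian pre-filter. The multiplicative update conserves
  total intensity and non-negativity. The PSF sigma should match the
  acquisition; for the synthetic phantoms the generator's blur is known
  and passed explicitly.
* **Segmentation** uses a global histogram threshold (Otsu by default; a
  fixed-quantile alternative is available). The method name for the
  original analysis is not recorded anywhere we can follow, so Otsu — the
  default "histogram threshold" of the field — was chosen and made
  configurable.
* **Cell mask**: from a cytosolic marker channel (threshold, Euclidean
  closing, 3D hole fill) when available; otherwise the filled interior of
  the membrane mask's outer surface, computed by flood-filling the
  exterior from the stack border.
* **Surface/t-system separation**: membrane signal within
  `surface_margin_um` (default 0.5 µm) of the cell boundary is surface
  sarcolemma, the rest is t-system. The margin is a design choice — no
  rule is published for the original analysis — and is exposed as
  configuration. Tubule signal inside the margin is unavoidably
  discarded, which biases ΔTT slightly upward near the surface; for
  elongated cells with tubules running along the long axis the bias is
  small (below ~5 % in the end-to-end tests).

Per-sample values are the arithmetic mean over at least 3 stacks
(`aggregate_sample_dtt()` warns below 3). An empty t-system yields a
flagged `NaN` rather than an error, so severely remodeled samples flow
through the pipeline.

## Phantoms

`gen_tsystem_stack()` renders a box-shaped cell (surface shell 0.3 µm)
with tubules as straight lines along the long axis on a square lattice
("full-lattice"), transverse planes ("sheets"), none ("surface-only") or
a user mask ("custom"). Two closed forms anchor the tests: parallel
planes spaced $d$ give mean distance $d/4$; a square lattice of lines
spaced $d$ gives $(d/6)(\sqrt2 + \ln(1+\sqrt2)) \approx 0.3826\,d$. At
0.1 µm voxels and spacings of 0.8–2 µm the discretized truth sits within
3 % of these values.

Two generator conventions matter and are deliberate:

* The tubule train is **centred** in the cell and kept one
  surface-thickness clear of the shell. Real t-tubules open into the
  sarcolemma, but a phantom line lying *inside* the surface shell is
  indistinguishable from surface and would be removed by any
  margin-based separation; the clearance makes the phantom test the
  metric rather than that degeneracy.
* Default spacing values (0.8–2.0 µm) span the ΔTT range reported for
  failing human myocardium (≈0.8–1.5 µm); remodeling is emulated by
  increasing the spacing.

Default desk-scale stacks are 64–70 voxels per axis at 0.1 µm isotropic
(the generator enforces ≥ 64); the full acquisition size
(1280×1280×300) is configurable but not needed for testing. The phantom
renders no optics beyond Gaussian blur and no Poisson/Gaussian noise
beyond the stated models; what passing tests show is that the chain
recovers known geometry under modest noise, not that it is robust to
every artifact of real confocal data (bleaching, scattering,
inhomogeneous staining).

# Morphometry

**Watershed segmentation** follows the distance-transform recipe: the
WGA image is thresholded, the distance transform of its complement is
computed, its regional maxima seed a morphological watershed, segments
whose perimeter contact fraction with the WGA mask falls below 0.6 are
removed, and the watershed is re-run from the surviving seeds until the
label set is stable (at most 5 iterations — the original publication
gives no count). Segments under 50 µm² are discarded as debris. The
contact threshold, iteration cap and minimum area are design choices
exposed as parameters.

**Orientation** is the dominant eigenvector of each segment's 2nd-order
central image moments, reported axially in [−90°, 90°). Near-isotropic
segments (eigenvalue ratio < 1.05) are flagged undefined rather than
assigned a noise direction.

**Axial statistics** use the doubled-angle convention: the main fiber
orientation is `0.5 * atan2(mean sin 2θ, mean cos 2θ)`, deviations are
axial differences, dispersion is reported both as the RMS of deviations
(default) and as the plain SD of signed deviations, and the disarray
fraction is the share deviating by more than 30°. The doubled-angle
default exists because plain SD misbehaves across the ±90° wrap; both
numbers are emitted since the original report does not say which
convention it used.

**Sarcomere length** is the reciprocal of the radial spatial frequency of
the 2D power-spectrum maximum inside the 1/2.5–1/1.5 µm⁻¹ band, after a
Hann window, with parabolic sub-bin interpolation on log power along both
frequency axes (sub-bin refinement is needed because desk-scale images
have a frequency resolution of ~0.026 µm⁻¹, coarser than the 0.02 µm
target accuracy). If the spectrum's global non-DC maximum lies outside
the band, or the in-band peak is below 20× the in-band median power, the
result is flagged undefined — never silently clipped into the band.

# Twitch kinetics and the FFR

The synthetic twitch is the double-exponential
$F(t) = A(e^{-t/\tau_d} - e^{-t/\tau_r})$, $\tau_d > \tau_r$, with
closed-form time to peak
$\mathrm{TTP} = \tau_r\tau_d\ln(\tau_d/\tau_r)/(\tau_d-\tau_r)$ and
numerically solved relaxation landmarks. Parameter definitions follow
the field's schematic: `f_max` is peak force above baseline, TTP runs
from onset to peak, TTR from peak to 90 % decay of the peak active
force, and CD90 from onset to 90 % decay, so CD90 = TTP + TTR by
construction. The 90 % level for TTR and CD90 is an interpretation (the
source schematic does not print the percentage) and both thresholds are
configurable.

Analysis choices:

* onset is the stimulus time when available, otherwise the crossing of
  baseline + 5 % of amplitude;
* baseline is the per-interval 10th percentile of (lightly smoothed)
  force;
* threshold crossings are linearly interpolated between samples
  (default sampling 1 kHz);
* a 5 ms centred moving average precedes peak/threshold detection. This
  suppresses the selection bias of a raw maximum under noise (which
  otherwise inflates mean `f_max` by ≈2σ) while moving the peak of a
  smooth twitch by ≪ 0.1 ms;
* fused twitches (force at window start above baseline + 20 % of
  amplitude) use the pre-peak minimum as local baseline and are flagged.

Per-frequency means use twitches whose stimulus falls in the last 30 s
of each 120 s interval; the FFR ratios are mean-`f_max` ratios at 1 vs
0.5 Hz and 2 vs 0.5 Hz (ratio > 1: positive FFR). Wall tension divides
force by the slice cross-section `width × (thickness − damaged margin)`,
5 mm × 0.25 mm = 1.25 mm² by default. Parameters from 2–8 neighboring
slices of one sample are combined by the component-wise median.

The generator's default twitch shapes accelerate with pacing frequency
(τ_r/τ_d = 0.05/0.15 s at 0.2–0.5 Hz, 0.035/0.10 s at 1 Hz,
0.02/0.055 s at 2 Hz). This is physiologically sensible
(frequency-dependent acceleration of relaxation) and keeps the residual
tail of each twitch below 0.1 % of peak at the next stimulus, honouring
the no-fusion precondition of the staircase analysis at 2 Hz.

# Statistical layer

* `linear_fit()` is ordinary least squares with R², an F-test against
  the intercept-only model, and pointwise 95 % confidence bands for the
  mean response.
* `interaction_fit()` fits `TTR = b1·ΔTT + b2·(NCX1·ΔTT)` **without an
  intercept** — the printed form of the published model has no constant
  term — and reports both raw coefficients and the factored form
  `b1·(ΔTT − ratio·NCX1·ΔTT)` with `ratio = −b2/b1`. R² follows the
  uncentered convention for no-intercept fits and says so in the output.
* `likelihood_ratio_test()` uses the Gaussian-errors closed form
  `n·ln(RSS_reduced/RSS_full)` against χ² with the coefficient-count
  difference as degrees of freedom. The reference is asymptotic; its
  type-I error is calibrated in the tests at n = 50 per replicate, where
  the 0.05 ± 0.02 band is attainable (at much smaller n the χ²
  approximation is anticonservative for any correct implementation).
* `t_test_unpaired()` defaults to the classic equal-variance Student
  form (Welch optional); two zero-variance groups with equal means give
  p = 1.
* `holm_bonferroni()` is the step-down adjustment (via `p.adjust`),
  checked against hand-computed vectors.
* `dichotomize_by_dtt()` splits at 1.05 µm with the boundary in the
  severe (≥) group.
* `normalize_densitometry()` divides a band by the geometric mean of
  Ponceau and GAPDH and then by the same-way-normalized inter-gel
  reference. NCX1 is quantified as the sum of its two bands.

## Cohort generator

`gen_cohort()` draws ΔTT ~ U(0.8, 1.5) µm (the reported cohort range)
and NCX1 ~ U(0.2, 3.0), and produces TTR from the interaction model with
coefficients (0.36, 0.069) plus Gaussian noise (default sd 0.005 s).
FFR ratios fall linearly with ΔTT and cross 1 at 1.05 µm (slope −0.8 per
µm), wall tension at 1 and 2 Hz declines with ΔTT while 0.2 and 0.5 Hz
are ΔTT-independent — the qualitative structure reported for the cohort;
the slopes and noise levels are this package's choices of realistic
magnitudes, fixed once, since only the interaction-model coefficients
are printed. With all noise set to zero the statistics module recovers
the generating coefficients exactly; this is a frozen test.

# Numerical and reproducibility notes

* All generators take a mandatory seed and restore the caller's RNG
  state; identical seeds give bit-identical outputs, and
  `run_pipeline()` is deterministic for a fixed config.
* Gaussian blurs use circular FFT convolution (contents stay clear of
  the border by construction in the generators); the Richardson-Lucy
  update clips at zero and guards divisions with 1e-12.
* Distances are always reported in µm using the stated voxel size;
  arrays are z-y-x ordered.
* Degenerate inputs have defined behavior: constant images refuse to
  threshold, empty tubule masks yield flagged `NaN` ΔTT, blank tile
  scans return a single segment with a warning, missing protocol
  frequencies yield flagged `NA` ratios.

## Problem sizes used in the shipped tests

Phantoms are 64–70 voxels per axis; mosaics are 100 cells at 40 px
tiles; traces are the full 480 s staircase at 1 kHz; the LRT
calibration uses 1000 replicates of n = 50; the end-to-end pipeline
runs two lattice phantoms, one mosaic, one striation image and two
traces. These sizes were chosen as the smallest at which the
discretization guarantees above hold.

# Known limitations

* The phantom geometry is idealized (straight tubules, box cell); it
  validates the metric and the chain, not biological variability.
* The surface-margin separation discards genuinely sub-sarcolemmal
  tubule signal; configurations with dense transverse sheets close to
  the cell ends will read high.
* The attenuation model is a single exponential gain; depth-varying
  scattering is not modeled.
* The LRT is asymptotic; for cohort-sized n (~13) its p-values are
  approximate (the published comparison at that n is reproduced in kind,
  not recalibrated).
* No nucleus exclusion, no tubule skeletonization/diameter analysis, no
  Ca²⁺ modeling, no mixed-effects slice-within-patient structure (the
  per-sample median makes rows independent).
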