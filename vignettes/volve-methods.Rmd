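---
title: "Voxel-wise regression mapping of lung ventilation and perfusion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise regression mapping of lung ventilation and perfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Free-breathing dynamic proton MRI of a coronal lung slice records, at a few
hundred milliseconds per frame, the periodic signal changes that breathing
and the cardiac cycle impose on the parenchyma: tissue (proton) density
falls as the alveoli inflate, and pulsatile blood volume modulates the
signal at the cardiac frequency. This package regresses every lung voxel's
signal time course against a physiological reference extracted from the
same series, instead of collapsing the series into two or three respiratory
states.

For ventilation, the reference is the *navigator*: the mean signal in a
30 x 5 voxel rectangle spanning the right hemidiaphragm, which rises and
falls with lung volume (maxima at end-expiration, minima at
end-inspiration). Both the navigator and each voxel course are expressed as
percentages of their temporal medians, so all quantities are relative and
the analysis is invariant to global intensity scaling. Three per-voxel
quantities are computed:

* **XCC** - the maximum Pearson cross-correlation between the voxel and the
  reference over integer lags spanning one full cycle; **CC** is the
  zero-lag value. XCC measures how tightly the voxel follows the reference,
  independent of any delay.
* **Lag** - the shift at which the maximum is attained, expressed as % of
  the respiratory cycle (ventilation) or in milliseconds (perfusion, where
  it is a blood-arrival time). Long lags and inverted responses mark
  delayed or paradoxical ventilation.
* **Grad** - the slope of a York (errors-in-variables) straight-line fit of
  voxel % signal on reference % signal. In healthy parenchyma both series
  are driven by the same relative volume change, so Grad is close to +1;
  paradoxical regions give Grad near -1. Because both series carry noise,
  ordinary least squares would attenuate the slope; the York solution
  evaluates the least-squares expressions at adjusted points and, with
  equal weights, reduces to the major-axis (Deming) solution, which
  preserves the slope magnitude even under a phase shift between the
  series.

The classical fractional ventilation `FV = (SI_exp - SI_insp) / SI_exp`,
computed from navigator-detected end-expiration/end-inspiration frames, is
provided as a comparison metric.

For perfusion the pipeline is identical except that the reference is a
user-supplied vessel ROI (aorta or main pulmonary artery) and both series
are high-pass filtered at 0.8 Hz rather than low-pass filtered at 0.6 Hz.

## Pipeline and parameters

`run_pipeline()` executes, in order: steady-state discard, global intensity
normalization, provisional segmentation for navigator-ROI placement,
navigator conditioning, mid-respiratory target selection, demons
registration, target-frame segmentation (analysis mask), voxel-wise
regression, histogram summaries. The defaults are the standard protocol
constants:

| parameter | default | meaning |
|---|---|---|
| `n_discard_frames` | 15 | frames dropped to reach steady state (512 acquired, 497 analysed) |
| `lowpass_hz` | 0.6 Hz | ventilation band cutoff, removes cardiac signal |
| `highpass_hz` | 0.8 Hz | perfusion band cutoff, removes respiratory signal |
| `nav_roi_fh_vox`, `nav_roi_rl_vox` | 30, 5 | navigator ROI extent (voxels) |
| `mad_k` | 3 | navigator outlier threshold in scaled MADs (1.4826 x MAD) |
| `vessel_factor` | 3 | vessel exclusion: brighter than 3x the parenchyma median |
| `mask_erode_vox` | 1 | analysis-mask rim erosion (see below) |
| `gmm_components` | 2 | mixture components for the Grad histogram |

The navigator ROI is centred on the right hemidiaphragm at one third of the
lateral-to-medial distance between the costophrenic and costocardiac
angles; the right lung is used to avoid cardiac contamination. The lag is
converted to % of cycle using the respiratory frequency estimated by
Fourier analysis of the conditioned navigator.

## Numerical choices

**Zero-phase filtering.** The band filters are 4th-order Butterworth
filters applied forward and backward, with odd-reflection edge padding.
Zero phase is essential: a causal filter's group delay would bias every lag
estimate. A consequence of the squared magnitude response is a ~9% droop
at 1.0 Hz after the 0.8 Hz high-pass; this cancels in Grad because voxel
and reference pass the identical filter.

**Normalization scale.** Each series is normalized by the median of its
*low-pass (baseline)* component rather than of the raw series. The median
of a raw series containing band-limited oscillations is not a pure baseline
estimate - when the cardiac frequency is near a harmonic of the respiratory
frequency the induced median shift becomes a systematic gain error on Grad.
Using the baseline median removes this coupling in both modalities; for the
high-pass (perfusion) series it is also the only well-defined scale, since
the filtered series itself has median near zero.

**Outlier handling.** Navigator frames beyond `mad_k` scaled MADs are
replaced by linear interpolation rather than deleted, preserving the
uniform time base that lag and frequency estimation require. If the MAD is
zero, only values differing from the median at all are candidates.

**Navigator from unregistered frames.** Registration warps every frame
onto the target and would freeze the diaphragm, destroying the navigator;
the navigator branch therefore reads the unregistered series while the
parenchyma branch reads the registered one.

**Target selection.** The registration target is the frame whose navigator
value is closest to the *median* navigator value (ties: earliest frame).
The median rather than the mean is used for robustness to outlier frames;
for near-sinusoidal breathing the two coincide within noise.

**Registration.** The demons solver (compiled, in `src/`) uses symmetric
intensity forces, a per-iteration displacement cap, fluid-like Gaussian
smoothing of the update field (sigma 1.0 voxel) and diffusion-like
smoothing of the total field (sigma 1.0), a 3-level pyramid, and bilinear
resampling. Because consecutive frames differ by well under a voxel of
diaphragm motion, each frame's solve warm-starts from the previous frame's
field, which dominates the order-of-magnitude speedup that keeps a
497-frame series around a few seconds at 64 x 64. Iterations stop at a
mean-update tolerance or when progress plateaus (the noise floor). Frames
whose mean displacement exceeds a quarter of the image extent are flagged
divergent and excluded from the regression rather than interpolated.

**Error weights for the York fit.** The variances of the navigator and
voxel series are not known a priori. Both are estimated with a robust
second-difference (Gasser-type) noise estimator, which cancels locally
linear signal and so leaks far less of the slow physiological oscillation
into the noise estimate than first differences would. With one scalar
error per series the York iteration has a closed form (the Deming slope
with `lambda = sy^2/sx^2`), which the map computation uses; the general
iterative York solver with per-point errors is exported as
`york_regression()` and the equivalence is asserted in the tests. A
config flag (`equal_weights`) forces unit weights (major-axis solution).

**Gradient at zero lag.** Grad is computed on the unshifted pair by
default: the York/Deming slope preserves magnitude under a phase shift, and
lagged, inverted regions then show *negative* gradients - which is exactly
the diagnostic signature sought in obstructed lungs. A config flag
(`grad_at_lag`) computes the slope at the XCC-optimal lag instead.

**Sub-frame lag refinement.** Parabolic interpolation over the correlation
peak's neighbours is on by default for perfusion (the cardiac period spans
only ~4 frames at 229 ms) and off for ventilation (~17 frames per cycle),
where integer-frame resolution (~5.7% of cycle) is already sufficient.

**Undefined voxels.** Voxels with zero variance, non-positive baseline, or
degenerate overlap carry NA and an `undefined_mask`; they are excluded from
all histograms. If more than half the mask is undefined the pipeline stops
with a data-quality error.

**Mask hygiene.** The analysis mask is the target-frame segmentation eroded
by one voxel. The outermost layer mixes parenchyma with chest wall and
mediastinum and concentrates residual registration effects at static
edges, which invert the apparent signal; eroding it removes a known
artifact band without touching the regional statistics. Vessel exclusion
(3x parenchyma median) has no quantitative basis in the ROI geometry and
is exposed as a parameter.

**Histogram metrics.** Skewness is the population moment estimator g1 (the
samples are thousands of voxels). The Grad histogram is fitted with a
two-component Gaussian mixture by EM initialized at the two physiological
modes (means +1 and -1, sds 0.5, equal weights; tolerance 1e-6, at most
500 iterations, sd-floor refit on collapse). The peak-area ratio (PAR) is
the weight of the more-negative component over the more-positive one, so
PAR grows with the paradoxical mode; "peak area" is interpreted as mixture
weight, the bin-width-independent quantity. The opposite orientation is
available (`par_orientation`), since either convention appears in practice.

## The synthetic phantom

No imaging data ship with the package; `generate_phantom()` renders a
2D+t series with known ground truth so that every stage is testable. It
emulates: a bright body oval with two dark lung fields; a diaphragm
rendered as an intensity step whose row follows a raised-cosine trace at
the respiratory frequency (sub-voxel partial-volume blending, optional
per-cycle amplitude jitter); parenchymal signal co-varying with lung
volume; a cardiac-frequency component and a bright mediastinal vessel with
strong cardiac modulation (the perfusion reference); rectangular defect
regions with reduced/zero/negative gradient, ventilation lags up to a full
cycle, and delayed cardiac arrival; and Rician magnitude noise (Gaussian
available for analytic tests).

The central calibration choice: the "true" gradient must be defined
relative to the navigator *as measured*, because the navigator's relative
amplitude depends on where the 30 x 5 ROI sits on the diaphragm. The
generator therefore renders the geometry, places the ROI with the same
rule the analysis uses, measures the relative navigator waveform, and
drives the parenchyma with `grad x` that waveform (a three-pass fixed
point, since lung voxels inside the ROI feed back into it). This makes the
%/% regression slope equal the injected gradient by construction, and lags
are injected by shifting the same waveform.

Default study conditions mirror the standard protocol: 512 frames at
229 ms (497 analysed), 0.25 Hz breathing, a 4-voxel diaphragm excursion on
a 64 x 64 grid, cardiac frequency 1.08 Hz (65 bpm), cardiac amplitude 5%
of tissue mean, and noise at SNR 20. The cardiac default is deliberately
incommensurate with the respiratory frequency: at exactly 1.0 = 4 x
0.25 Hz the two waveforms phase-lock and their sum's sample median shifts
systematically, which no real physiology exhibits. The 64 x 64 matrix and
497 frames are the validation problem size used throughout the tests and
the acceptance script; the pipeline itself is resolution-agnostic.

What the phantom does *not* emulate: in-plane parenchymal tissue motion
(only the diaphragm boundary moves), vascular trees, B0/B1 or T2*
physics, coil shading, and breathing irregularity beyond per-cycle
amplitude jitter. Passing the recovery tests therefore demonstrates the
correctness of the signal-processing chain - registration convergence on a
moving step edge, band separation, lag and slope recovery, histogram
metrics - not robustness to every property of in-vivo data.

## Repeatability statistics

`bland_altman()` reports the mean difference and the 95% limits of
agreement (mean +/- 1.96 x n-1 standard deviation of the differences); the
confidence interval of the mean difference is reported separately because
the two are often conflated. `coefficient_of_variation()` uses the
two-point n-1 convention `sd = |difference| / sqrt(2)` with the absolute
mean, and summarizes subjects by the median CoV. Group comparisons
(Kruskal-Wallis with pairwise Wilcoxon post hocs, Spearman correlation)
are delegated to the standard routines via `group_tests()`.

## Known limitations

* Single 2D coronal slice; no 3D extension.
* Intensity-driven registration can misread genuine signal modulation at
  static high-contrast edges as motion; the one-voxel rim erosion bounds
  but does not eliminate this.
* The error model behind the York weights is a single scalar noise level
  per series; heteroscedastic frames (e.g. interpolated outliers) are not
  down-weighted individually.
* With a low-amplitude or irregular navigator the Fourier frequency
  estimate may be flagged low-confidence; lag units then inherit that
  uncertainty.
* DICOM input is not supported; convert to NIfTI first.
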