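---
title: "Quantitative susceptibility mapping with qsmr: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative susceptibility mapping with qsmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical model

Gradient-recalled-echo (GRE) MRI phase accrues in proportion to the local
deviation of the main magnetic field. That deviation is generated by the
spatial distribution of tissue magnetic susceptibility $\chi(\mathbf r)$
(in ppm): the field is the convolution of $\chi$ with the unit magnetic
dipole response, which in the spatial-frequency domain is a pointwise
multiplication with

$$D(\mathbf k) = \frac{1}{3} - \frac{(\mathbf k \cdot \hat{\mathbf b})^2}{|\mathbf k|^2},$$

where $\hat{\mathbf b}$ is the main-field direction. $D$ vanishes on the
cone at $\arccos\sqrt{1/3} \approx 54.7^\circ$ from $\hat{\mathbf b}$ (the
magic angle), so recovering $\chi$ from the field is an ill-posed
deconvolution. The measured voxel phase at echo time $TE$ is

$$\varphi = (2\pi f \cdot TE + \varphi_0) \bmod 2\pi,$$

with $f$ the field shift in Hz and $\varphi_0$ a TE-independent offset
(receive-chain and non-field contributions). Reconstruction therefore
proceeds through: field estimation across echoes, removal of $\varphi_0$
and of phase wraps, masking, removal of the *background* field generated by
sources outside the brain (air cavities, ~9 ppm away from tissue), and
regularized dipole inversion of the remaining *tissue* field. Susceptibility
is only defined up to a constant, so maps are finally referenced to an
internal region.

## The pipeline, stage by stage

### Field estimation

`fit_complex_multiecho()` fits $M(TE)\,e^{i(2\pi f\,TE + \varphi_0)}$ to
the complex signal per voxel (three or more echoes required), by
Gauss-Newton on $(f, \varphi_0)$ initialized from wrapped temporal phase
differences; magnitudes are taken from the data. For uniform echo spacing
$\Delta TE$ the fitted $f$ is reported as the principal value within
$\pm 1/(2\Delta TE)$ — temporal sampling cannot distinguish faster
precession — and the residual spatial ambiguity is resolved later by
spatial unwrapping of the pseudo-phase $2\pi f \Delta TE$. The fit yields a
standard-error map of $f$ ("noise map"); its inverse, min–max normalized,
is the quality map used for masking and unwrapping order.

`combine_weighted_average()` is the two-or-more-echo alternative: each
echo's offset-corrected phase slope is averaged with weights
$w_e = TE_e\,M_e^2$. The weight choice is ours: it is the inverse
phase-variance weighting under high-SNR complex Gaussian noise (phase sd
$\propto 1/M$, slope division by $TE$); magnitude-only and equal weights
are available for comparison. $\varphi_0$, when not supplied, comes from
linear extrapolation of the first two unwrapped echoes to $TE = 0$.

### Spatial unwrapping

`unwrap_spatial()` is an exact, path-based region-growing unwrapper
(implemented in C++): each 6-connected mask component grows from its
highest-quality voxel in descending quality order, adding to each new voxel
the integer multiple of $2\pi$ that best matches its already-unwrapped
neighbour. Output minus input is therefore an exact multiple of $2\pi$
everywhere — the property that distinguishes exact unwrappers from
Laplacian approximations, whose smooth errors propagate into susceptibility
values. Ties in quality are broken by voxel index, and the seed is the
maximum-quality voxel, so the result is fully deterministic. Disconnected
mask components are internally consistent but carry arbitrary relative
$2\pi$ offsets; the component count is reported.

### Masking

`finalize_masks()` implements the four-stage workflow: Mask 1 (initial
brain) from the magnitude image; Mask 2 (reliable phase) by thresholding
the inverse noise map at `factor` (default 1.0, with 1.2 as a stricter
option) times its field-of-view mean; Mask 3 = holes-filled intersection,
used for background-field removal; Mask 4 = Mask 3 eroded (default 1 voxel
after V-SHARP, 0 after PDF) with the interior holes optionally re-excluded
for inversion. Holes are background components (6-connectivity, a
deliberate strict choice that fills thin-necked cavities) not connected to
the volume border. Two display conventions circulate — eroded mask with or
without holes filled; we default to holes-filled display (`display`) and
also return the holes-excluded variant (`display_noholes`).

The built-in brain extractor (global Otsu threshold, largest connected
component, morphological closing of radius 2) is deliberately simple so the
package is self-contained and testable; on real data a dedicated tool is
preferable and can be attached via the `external` hook.

### Background-field removal

Fields from sources outside the mask are harmonic inside it, hence
invariant under the spherical mean value (SMV) average. `vsharp()` applies
$(\delta - SMV_r)$ with, at each voxel, the largest radius $r$ whose sphere
fits inside Mask 3 (default radii 12 mm down to 1 mm in 1 mm steps; radii
smaller than a voxel are dropped), then inverts the filter by truncated
deconvolution of $(1 - \widehat{SMV})$ at the *largest* radius with
threshold 0.05. Both the single-largest-radius deconvolution and the 0.05
threshold are our choices (standard SHARP practice; both recorded in
provenance and configurable). The deconvolution zeroes the DC bin, so
V-SHARP output is mean-free over its validity mask — consistent with
relative referencing. `pdf_background()` instead fits effective sources
supported outside Mask 3 by noise-weighted least squares (conjugate
gradients on the normal equations, relative-residual tolerance $10^{-6}$,
200-iteration cap with a warning and best iterate on non-convergence — at
the default phantom size the cap typically triggers with suppression
already at ~99.9%). V-SHARP degrades gracefully with imperfect masks but
erodes the boundary; PDF keeps the full mask but needs a good one. No
polynomial detrending is applied after either method by default.

### Dipole inversion

`tkd_invert()` is the thresholded k-space division baseline (threshold
0.2, our default; the method is conventionally quoted without parameters).
`tv_invert()` solves

$$\hat\chi = \arg\min_\chi \|w(\Delta B_t - d * \chi)\|_2^2 + \lambda\,TV(\chi)$$

by alternating-direction splitting with auxiliary variables for the
gradient (isotropic TV; consistency weight $\mu$ = 0.05) and the
dipole-convolved field, making every subproblem closed-form. Defaults
$\lambda = 5\times10^{-4}$, $\mu = 0.05$ operate on the ppm scale — the
field is converted from Hz to ppm *before* inversion so these magnitudes
match common practice. The gradient operator is a periodic (circular)
forward difference so the $\chi$-subproblem stays diagonal in k-space; with
the object masked well inside the field of view this is equivalent to a
Neumann boundary in practice. The data-fidelity weight defaults to the
binarized mask; `fidelity_weight()` builds an inverse-noise weight
normalized to its in-mask median and clipped at the 99th percentile.
Isotropic TV was chosen over anisotropic — gradient-sparsity flavours are
expected to behave similarly here. $D(0)=0$ fixes the arbitrary constant,
consistent with referencing. The solver is deterministic; the objective is
tracked and a sustained (five-iteration) increase beyond 1.5x the running
minimum raises a divergence error, while the transient oscillation normal
for splitting methods is tolerated.

`lcurve_select()` sweeps $\lambda$, records (log residual norm, log TV
norm) and returns the maximum-curvature (three-point discrete) interior
point, with the full table for reporting.

### Referencing, ROI analysis, QC

`reference_map()` subtracts the mean over a reference region (default:
whole brain, i.e. the validity mask — stable and requiring no extra
segmentation; a CSF mask can be supplied as an ROI). Re-referencing between
regions is pure arithmetic on relative means (`rereference_value()`):
differences between ROI means are invariant to the reference choice, which
is the property that makes values comparable across pipelines. `roi_stats()`
never lets zero-filled invalid voxels enter a mean — ROIs are intersected
with the validity mask and exclusions counted. `qc_screen()` applies
heuristic flags (ROI means beyond ±0.3 ppm or a cohort z-score of 3 when at
least 5 subjects are available, a spike of exact zeros inside the mask, more
than 1% of voxels beyond 0.5 ppm); the thresholds are exposed in the
configuration and recorded, since published screening strategies name the
ideas but not numbers.

### Protocol calculators and reporting

`ernst_angle()`, `echo_train()` and `fatwater_shift_pixels()` implement
the standard planning formulas with the usual presets ($T_1$ = 650 / 850 /
1220 ms and putamen $T_2^*$ = 55 / 30 / 16 ms at 1.5 / 3 / 7 T; fat-water
shift 3.5 ppm at 42.577 MHz/T). The echo-train check warns (rather than
fails) when the last TE is within 10% below the target $T_2^*$: the widely
used five-echo 3 T protocol ends at 28.57 ms against a 30 ms putamen
target, and that configuration is considered acceptable. `build_report()`
assembles the hardware / sequence / pipeline reporting items with
essential-vs-optional markings, flags missing essentials, lists every
parameter value even when it is a default, and emits a ready-to-paste
methods paragraph.

## The numerical phantom

`phantom_preset()` builds the validation scene: a 64³ grid of 2 mm voxels
(128 mm field of view — head-scale, so the largest SMV radius is ~0.3 of
the brain radius as in a real acquisition), a brain sphere of radius 40 mm
($\chi = 0$, $T_2^*$ = 50 ms), two 10 mm target spheres at $+0.1$ and
$-0.1$ ppm, a dim short-$T_2^*$ shell around the brain, and an 8 mm air
sphere 9 ppm away from tissue just outside the head that generates a
realistic, partly aliasing background field. The TE = 0 offset
$\varphi_0$ is a low-order polynomial (amplitude ~0.3-0.4 rad) — published
analyses note harmonic and non-harmonic parts without giving a form, and a
smooth polynomial is the minimal testable stand-in. Noise is complex
Gaussian at first-echo SNR 50 added to the complex signal, not to the
phase, so phase noise is magnitude-dependent and non-Gaussian as in real
data. The forward field is computed with the k-space kernel after 2x
zero-padding per axis (the dipole field is long-range; circular convolution
would otherwise alias), and every intermediate — total, tissue and
background fields, $\varphi_0$, brain mask — is retained as ground truth.

What the phantom does *not* emulate: microstructural anisotropy and
orientation-dependent frequency shifts, nonlinear phase evolution from
sub-voxel compartments, flow, coil-combination residuals, k-space
undersampling, and realistic anatomy. Passing tests therefore demonstrate
correctness of the implemented operators and of their composition under
the stated signal model, not clinical performance.

## Numerical choices and degenerate inputs

* Phase rescaling maps the stored minimum to $-\pi$ and divides by the
  range plus one quantization step for integer scales, avoiding a
  duplicate $\pm\pi$ bin; the wrap into $[-\pi, \pi)$ is half-open
  everywhere. Which end of a vendor's integer scale corresponds to
  $+\pi$ is a convention, not a standard — the `phase_sign` flag (+1
  default, paramagnetic-positive) covers the polarity.
* Volumes are kept in the file's native axis order; the NIfTI header is
  the single source of truth for geometry, and the B0 direction is
  expressed in image axes (oblique slabs must invert with the matching
  tilted kernel — mismatching it measurably degrades reconstruction, and a
  test asserts this).
* All-zero-magnitude voxels get quality 0, zero field and infinite noise;
  constant reliability maps threshold to "keep everything" with a warning;
  empty masks are errors.
* Problem sizes in the test suite (64³ full pipeline, 32³-48³ for solver
  properties) were chosen so the whole suite runs in a few minutes while
  every sphere is still well resolved (radius ≥ 5 voxels).

## Known limitations

* The built-in brain extractor assumes a bright, connected brain on a dark
  background; real data should use a dedicated tool via the external hook.
* V-SHARP accuracy degrades within the variable-radius boundary zone, and
  PDF within ~2 voxels of the mask edge; both are documented behaviours of
  the methods, and the validity masks make the affected regions explicit.
* Laplacian unwrapping, LBV, single-step/total-field inversion,
  morphology-prior or CSF-regularized inversion, and susceptibility source
  separation are out of scope; the stage interfaces are the extension
  points.
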