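# qsmr — quantitative susceptibility mapping for multi-echo GRE MRI

Tissue magnetic susceptibility χ (in ppm) perturbs the main field of an MR
scanner, and that perturbation is encoded in the phase of gradient-recalled
echo (GRE) acquisitions. Recovering χ from multi-echo phase is a chain of
inverse problems: the measured phase is wrapped modulo 2π and offset by a
TE-independent term φ₀; the field it encodes mixes the wanted *tissue*
contribution with a much larger *background* field from sources outside the
brain (≈ 9 ppm air–tissue contrast); and the remaining tissue field relates
to χ through convolution with the unit dipole kernel, whose spatial-frequency
form

    D(k) = 1/3 − (k·b̂)² / |k|²

vanishes on the magic-angle cone (≈ 54.7° from the field direction), making
the final deconvolution ill-posed.

`qsmr` implements the full recommended reconstruction chain as a tested R
package, for researchers who want a transparent, self-contained QSM pipeline
or reference implementations of its individual stages:

* phase rescaling to [−π, π) with vendor sign handling, NIfTI + JSON-sidecar
  I/O (`rescale_phase`, `load_multiecho`, `write_volume`)
* nonlinear complex multi-echo field fitting with noise/quality maps, and
  weighted echo averaging (`fit_complex_multiecho`,
  `combine_weighted_average`)
* exact (path-based, quality-guided) spatial phase unwrapping
  (`unwrap_spatial`)
* the four-stage mask workflow: initial brain mask, reliable-phase mask,
  hole-filled background-removal mask, eroded inversion mask
  (`initial_brain_mask`, `reliable_phase_mask`, `finalize_masks`)
* background-field removal by V-SHARP (variable-radius spherical mean value
  filtering) and PDF (projection onto dipole fields) (`vsharp`,
  `pdf_background`)
* dipole inversion by thresholded k-space division and total-variation
  regularized optimization, with L-curve λ selection (`tkd_invert`,
  `tv_invert`, `lcurve_select`, `scale_to_ppm`)
* internal referencing, re-referencing arithmetic, ROI statistics restricted
  to valid voxels, QC screening (`reference_map`, `rereference_value`,
  `roi_stats`, `qc_screen`)
* protocol calculators (Ernst angle, echo train vs T₂*, fat–water shift) and
  a consensus-style reporting bundle (`ernst_angle`, `echo_train`,
  `fatwater_shift_pixels`, `build_report`)
* a numerical phantom with ground truth at every intermediate stage
  (`phantom_preset`, `simulate_multiecho`), so the whole chain is validated
  without any external data
* `run_pipeline()`, which chains everything with provenance, and a thin CLI
  (`inst/cli/qsm.R`) with `phantom`, `run`, `fieldmap`, `convert` and
  `protocol-check` subcommands.

## Worked example

Reconstruct the built-in phantom (64³ voxels, 2 mm, five echoes at 3 T,
SNR 50) and read off the two target spheres, whose true susceptibilities
are +0.1 and −0.1 ppm:

```r
library(qsmr)

cfg <- pipeline_config(seed = 1)        # every stage parameter has a default
res <- run_pipeline(cfg)                # phantom preset is the default input

tm <- phantom_target_masks()
rois <- list(roi_definition("paramagnetic_target", tm$para),
             roi_definition("diamagnetic_target",  tm$dia))
print(res$chi)
roi_stats(res$chi, rois)
```

```
<qsm_chimap> tv inversion, grid 64x64x64
referenced to: wholebrain (mean 5.94e-05 ppm subtracted)
                label mean_ppm  sd_ppm n_voxels n_excluded note
1 paramagnetic_target   0.0985 0.00217      280          0
2  diamagnetic_target  -0.0963 0.00173      280          0
```

The recovered means sit within 4% of the ground truth (TV regularization
trades a little amplitude for noise suppression), the standard deviations
show the in-ROI spread, and `n_excluded = 0` confirms both ROIs lie inside
the map's validity mask. `res$report` carries every reporting item
(algorithms and all parameter values, including defaults) plus a
ready-to-paste methods paragraph, and `res$qc` is a table of screening
flags — clean here.

The protocol calculators evaluate the standard planning formulas:

```r
ernst_angle(0.033, t1_preset(3))   # 15.9  (degrees, TR 33 ms at 3 T)
magic_angle()                      # 54.7  (degrees, kernel root-finding)
scale_to_ppm(1, 3, 0.005)          # 0.2492 (ppm for 1 rad at 3 T, 5 ms)
```

See `vignettes/qsm-methods.Rmd` for the models, parameter choices and
limitations.

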