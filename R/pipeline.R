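stage_record <- function(stage, algorithm, params, warnings = character()) {
  list(stage = stage, algorithm = algorithm, params = params,
       warnings = warnings, timestamp = format(Sys.time(), tz = "UTC"))
}

#' Run the full recommended QSM reconstruction chain
#'
#' load (or simulate) -> nonlinear complex fit -> exact spatial unwrapping
#' -> four-stage masks -> background-field removal (V-SHARP default, PDF
#' optional) -> dipole inversion (TV default, TKD optional) -> internal
#' referencing -> ROI statistics / QC -> reporting bundle.  The run is
#' fully deterministic given the configuration (which includes the phantom
#' seed); every intermediate can be written as NIfTI for inspection.
#'
#' @param config A [pipeline_config()].
#' @param data A [multiecho_dataset()], or `NULL` to run the built-in
#'   phantom preset.
#' @param phantom Optional [phantom_spec()] used when `data` is `NULL`
#'   (default: `phantom_preset("default", seed = config$seed)`).
#' @param rois Optional list of [roi_definition()]s for the ROI report.
#' @param output_dir Optional directory; when given, intermediates (field,
#'   masks, tissue field, chi) and the report are written there.
#' @return List with `chi` (referenced `qsm_chimap`), `fieldmap`, `masks`,
#'   `tissue`, `roi_report`, `qc`, `report` and `provenance`.  When run on
#'   the phantom, `truth` holds the ground-truth intermediates.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL,
                         phantom = NULL, rois = NULL, output_dir = NULL) {
  prov <- list()
  truth <- NULL
  if (is.null(data)) {
    if (is.null(phantom)) phantom <- phantom_preset(seed = config$seed)
    meta <- phantom_meta()
    sim <- simulate_multiecho(phantom, meta)
    data <- sim$data
    truth <- sim$truth
    prov <- c(prov, list(stage_record("phantom", "built-in numerical phantom",
      list(snr = phantom$snr, seed = phantom$seed,
           shape = phantom$shape))))
  }
  meta <- data$meta

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # 1. field estimation
  fm <- run_stage("fieldmap", {
    if (config$fieldmap_method == "nlfit")
      fit_complex_multiecho(data, max_iter = config$fit_max_iter,
                            tol = config$fit_tol)
    else combine_weighted_average(data, weights = config$weight_scheme)
  })
  prov <- c(prov, list(stage_record("fieldmap",
    if (config$fieldmap_method == "nlfit")
      "nonlinear complex multi-echo fit" else "weighted echo averaging",
    list(method = config$fieldmap_method))))

  # 2. masking
  masks <- run_stage("masking", {
    magvol <- if (config$mask_magnitude == "combined")
      sqrt(Reduce(`+`, lapply(data$magnitude, function(m) m^2)))
    else data$magnitude[[1]]
    m1 <- initial_brain_mask(magvol,
                             closing_radius = config$mask_closing_radius)
    m2 <- reliable_phase_mask(fm, factor = config$mask_quality_factor)
    finalize_masks(m1, m2, erosion_voxels = config$mask_erode_voxels,
                   reintroduce_holes = config$mask_reintroduce_holes)
  })
  prov <- c(prov, list(stage_record("masking", "four-stage mask workflow",
    list(quality_factor = config$mask_quality_factor,
         erode_voxels = config$mask_erode_voxels,
         reintroduce_holes = config$mask_reintroduce_holes))))

  # 3. spatial unwrapping of the fitted field (resolves spatial aliasing of
  # the per-voxel principal value via the pseudo-phase at one echo spacing)
  field_hz <- run_stage("unwrap", {
    if (length(meta$te) >= 2) {
      dte <- diff(meta$te)[1]
      pseudo <- wrap_phase(2 * pi * fm$field * dte)
      unw <- unwrap_spatial(pseudo, fm$quality, masks$mask3)
      out <- fm$field
      out[masks$mask3] <- unw[masks$mask3] / (2 * pi * dte)
      # keep the brain-median turn count at zero so the bulk field is the
      # principal value
      med <- stats::median(out[masks$mask3] - fm$field[masks$mask3])
      out[masks$mask3] <- out[masks$mask3] -
        round(med * dte) / dte
      out
    } else fm$field
  })
  prov <- c(prov, list(stage_record("unwrap",
    "quality-guided region-growing unwrapping", list())))

  # 4. background-field removal
  tissue <- run_stage("background", {
    if (config$bg_method == "vsharp")
      vsharp(field_hz, masks$mask3, radii_mm = config$vsharp_radii_mm,
             tsvd_threshold = config$vsharp_tsvd,
             voxel_size = meta$voxel_size)
    else
      pdf_background(field_hz, masks$mask3,
                     voxel_size = meta$voxel_size,
                     b0_direction = meta$b0_direction,
                     tol = config$pdf_tol, max_iter = config$pdf_max_iter)
  })
  prov <- c(prov, list(stage_record("background",
    toupper(config$bg_method),
    if (config$bg_method == "vsharp")
      list(radii_mm = config$vsharp_radii_mm, tsvd = config$vsharp_tsvd)
    else list(tol = config$pdf_tol, max_iter = config$pdf_max_iter))))

  # 5. dipole inversion on the intersection of tissue validity and Mask 4
  inv_mask <- tissue$valid_mask & masks$mask4
  kernel <- dipole_kernel(dim(field_hz), meta$voxel_size, meta$b0_direction)
  chi <- run_stage("inversion", {
    if (config$inversion_method == "tv")
      tv_invert(tissue$tissue_field, kernel,
                weight_w = fidelity_weight(fm$noise, inv_mask),
                lambda_reg = config$tv_lambda,
                mu_consistency = config$tv_mu,
                max_iter = config$tv_max_iter, tol = config$tv_tol,
                meta = meta, valid_mask = inv_mask)
    else
      tkd_invert(tissue$tissue_field, kernel,
                 threshold = config$tkd_threshold, meta = meta,
                 valid_mask = inv_mask)
  })
  prov <- c(prov, list(stage_record("inversion",
    if (config$inversion_method == "tv") "TV-regularized inversion"
    else "thresholded k-space division",
    if (config$inversion_method == "tv")
      list(lambda = config$tv_lambda, mu = config$tv_mu)
    else list(threshold = config$tkd_threshold))))

  # 6. referencing
  chi <- run_stage("referencing", reference_map(chi, "wholebrain"))
  prov <- c(prov, list(stage_record("referencing", "whole-brain referencing",
    list(region = "wholebrain"))))

  # 7. analysis + QC + report
  roi_report <- if (!is.null(rois)) roi_stats(chi, rois) else NULL
  qc <- qc_screen(chi, rois = rois,
                  z_threshold = config$qc_z_threshold,
                  abs_bound_ppm = config$qc_abs_bound_ppm,
                  streak_fraction = config$qc_streak_fraction,
                  streak_ppm = config$qc_streak_ppm)
  report <- build_report(meta, config, prov)
  prov <- c(prov, list(stage_record("report", "reporting bundle", list())))

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_volume(field_hz, meta, file.path(output_dir, "total_field_hz.nii.gz"))
    write_volume(array(as.numeric(masks$mask3), dim(field_hz)), meta,
                 file.path(output_dir, "mask3.nii.gz"))
    write_volume(array(as.numeric(masks$mask4), dim(field_hz)), meta,
                 file.path(output_dir, "mask4.nii.gz"))
    write_volume(tissue$tissue_field, meta,
                 file.path(output_dir, "tissue_field_hz.nii.gz"))
    write_volume(chi$chi, meta, file.path(output_dir, "chi_ppm.nii.gz"))
    write_report(report, file.path(output_dir, "report.json"))
    write_report(report, file.path(output_dir, "report.md"))
  }

  list(chi = chi, fieldmap = fm, field_hz = field_hz, masks = masks,
       tissue = tissue, roi_report = roi_report, qc = qc, report = report,
       provenance = prov, truth = truth, meta = meta, config = config)
}
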