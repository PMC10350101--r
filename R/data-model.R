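#' Acquisition metadata for a multi-echo GRE dataset
#'
#' Bundles the scan parameters the pipeline needs: main field strength, echo
#' times, repetition time, flip angle, voxel size, the direction of the main
#' field expressed in image axes, and the vendor phase-sign convention.
#'
#' @param field_strength Main magnetic field strength B0 in tesla (> 0).
#' @param te Echo times in seconds, strictly increasing.
#' @param tr Repetition time in seconds.
#' @param flip_angle Excitation flip angle in degrees.
#' @param voxel_size Voxel dimensions in mm, length-3.
#' @param b0_direction Unit vector of the main field in image axes
#'   (default `c(0, 0, 1)`, i.e. along the third array axis).
#' @param phase_sign `+1` or `-1`; vendor convention relating stored phase to
#'   field-induced phase accrual.  With `+1`, relatively paramagnetic tissue
#'   (positive susceptibility) accrues positive phase.
#' @param vendor,model,software Free-text scanner identification used only in
#'   reporting.
#' @return An object of class `qsm_meta`.
#' @export
acquisition_meta <- function(field_strength, te, tr = NA_real_,
                             flip_angle = NA_real_,
                             voxel_size = c(1, 1, 1),
                             b0_direction = c(0, 0, 1),
                             phase_sign = 1,
                             vendor = NA_character_, model = NA_character_,
                             software = NA_character_) {
  stopifnot(is.numeric(field_strength), length(field_strength) == 1)
  if (!(field_strength > 0)) stop("field_strength must be > 0")
  te <- as.numeric(te)
  if (length(te) < 1 || any(diff(te) <= 0))
    stop("te must be strictly increasing")
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0))
  b0_direction <- as.numeric(b0_direction)
  stopifnot(length(b0_direction) == 3)
  if (abs(sqrt(sum(b0_direction^2)) - 1) > 1e-6)
    stop("b0_direction must have unit norm (tolerance 1e-6)")
  if (!phase_sign %in% c(1, -1)) stop("phase_sign must be +1 or -1")
  structure(
    list(field_strength = field_strength, te = te, tr = tr,
         flip_angle = flip_angle, voxel_size = as.numeric(voxel_size),
         b0_direction = b0_direction, phase_sign = phase_sign,
         vendor = vendor, model = model, software = software),
    class = "qsm_meta")
}

#' @export
print.qsm_meta <- function(x, ...) {
  cat("<qsm_meta> B0 =", x$field_strength, "T;",
      length(x$te), "echoes; TE =",
      paste(signif(x$te * 1e3, 4), collapse = ", "), "ms;",
      "voxel =", paste(x$voxel_size, collapse = "x"), "mm\n")
  invisible(x)
}

# uniform echo spacing test used in loading and reporting
has_uniform_spacing <- function(te, tol = 1e-6) {
  if (length(te) < 3) return(TRUE)
  d <- diff(te)
  max(abs(d - d[1])) <= tol * max(d)
}

#' Multi-echo magnitude/phase dataset
#'
#' @param magnitude List of nonnegative 3D arrays, one per echo.
#' @param phase List of 3D arrays in radians within `[-pi, pi)`, one per echo.
#' @param meta [acquisition_meta()] whose `te` length matches the echo count.
#' @return An object of class `qsm_multiecho` with elements `magnitude`,
#'   `phase`, `meta`, `uniform_spacing` and a character vector `warnings`.
#' @export
multiecho_dataset <- function(magnitude, phase, meta) {
  if (is.array(magnitude)) magnitude <- list(magnitude)
  if (is.array(phase)) phase <- list(phase)
  if (length(magnitude) != length(phase))
    stop("echo-count mismatch: ", length(magnitude), " magnitude vs ",
         length(phase), " phase volumes")
  if (length(meta$te) != length(phase))
    stop("sidecar lists ", length(meta$te), " echo times for ",
         length(phase), " echoes")
  shapes <- unique(lapply(c(magnitude, phase), dim))
  if (length(shapes) != 1) stop("all echoes must share one grid shape")
  for (p in phase) {
    if (any(p < -pi - 1e-9 | p >= pi + 1e-9))
      stop("phase values must lie within [-pi, pi); run rescale_phase() first")
  }
  if (any(vapply(magnitude, function(m) any(m < 0), logical(1))))
    stop("magnitude must be nonnegative")
  warn <- character()
  uniform <- has_uniform_spacing(meta$te)
  if (!uniform) warn <- c(warn, "non-uniform echo spacing")
  structure(
    list(magnitude = magnitude, phase = phase, meta = meta,
         uniform_spacing = uniform, warnings = warn),
    class = "qsm_multiecho")
}

#' @export
print.qsm_multiecho <- function(x, ...) {
  cat("<qsm_multiecho>", length(x$phase), "echoes, grid",
      paste(dim(x$phase[[1]]), collapse = "x"), "\n")
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Rescale stored phase to radians in `[-pi, pi)`
#'
#' Exported phase is often stored on an integer scale (e.g. 0..4095).  This
#' maps `stored_min` to `-pi` with a half-open upper bound: integer scales
#' divide by the range plus one quantization step so that no value lands on
#' the duplicate `+pi` bin; float scales already spanning `2*pi` map
#' identically onto themselves.  The vendor `phase_sign` is applied after
#' rescaling and the result re-wrapped into `[-pi, pi)`.
#'
#' @param raw Numeric array (or vector) of stored phase values.
#' @param stored_min,stored_max Stored value range; `stored_max > stored_min`.
#' @param phase_sign `+1` or `-1`.
#' @return Array of radians, strictly within `[-pi, pi)`.
#' @export
rescale_phase <- function(raw, stored_min, stored_max, phase_sign = 1) {
  if (!(stored_max > stored_min))
    stop("degenerate stored range: stored_max must exceed stored_min")
  if (!phase_sign %in% c(1, -1)) stop("phase_sign must be +1 or -1")
  is_integer_scale <- isTRUE(all.equal(stored_min, round(stored_min))) &&
    isTRUE(all.equal(stored_max, round(stored_max))) &&
    (stored_max - stored_min) > 2 * pi + 1e-9
  step <- if (is_integer_scale) 1 else 0
  rng <- (stored_max - stored_min) + step
  ph <- -pi + 2 * pi * (raw - stored_min) / rng
  ph <- ph * phase_sign
  wrap_phase(ph)
}

# wrap radians into [-pi, pi)
wrap_phase <- function(x) {
  out <- (x + pi) %% (2 * pi) - pi
  out[out >= pi] <- -pi   # guard against numeric round-up at the boundary
  out
}

#' Load a multi-echo dataset from NIfTI files plus a JSON sidecar
#'
#' The sidecar is a flat key-value JSON file with the fields
#' `EchoTimes_s`, `FieldStrength_T` (required) and optionally
#' `RepetitionTime_s`, `FlipAngle_deg`, `PhaseSign`, `B0Direction`,
#' `Vendor`, `ScannerModel`, `SoftwareVersion`.  Voxel size and, unless
#' overridden by the sidecar, the B0 direction are derived from the NIfTI
#' header: B0 is taken along the scanner z-axis and expressed in image axes
#' through the rotation part of the affine.
#'
#' @param magnitude_paths,phase_paths Equal-length character vectors of NIfTI
#'   paths, one per echo.
#' @param sidecar_path Path to the JSON sidecar.
#' @return A [multiecho_dataset()].
#' @export
load_multiecho <- function(magnitude_paths, phase_paths, sidecar_path) {
  if (length(magnitude_paths) != length(phase_paths))
    stop("echo-count mismatch: ", length(magnitude_paths), " magnitude vs ",
         length(phase_paths), " phase files")
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (req in c("EchoTimes_s", "FieldStrength_T")) {
    if (is.null(side[[req]]))
      stop("sidecar is missing required metadata field: ", req)
  }
  mag <- lapply(magnitude_paths, function(p) unclass_nifti(RNifti::readNifti(p)))
  ph <- lapply(phase_paths, function(p) unclass_nifti(RNifti::readNifti(p)))
  hdr <- RNifti::niftiHeader(RNifti::readNifti(magnitude_paths[1]))
  voxel <- abs(hdr$pixdim[2:4])
  b0 <- side$B0Direction
  if (is.null(b0)) {
    rot <- RNifti::xform(RNifti::readNifti(magnitude_paths[1]))[1:3, 1:3]
    # scanner z expressed in image axes; columns of rot map image axes to world
    b0 <- solve(rot, c(0, 0, 1))
    b0 <- b0 / sqrt(sum(b0^2))
  }
  meta <- acquisition_meta(
    field_strength = side$FieldStrength_T,
    te = side$EchoTimes_s,
    tr = side$RepetitionTime_s %||% NA_real_,
    flip_angle = side$FlipAngle_deg %||% NA_real_,
    voxel_size = voxel,
    b0_direction = b0,
    phase_sign = side$PhaseSign %||% 1,
    vendor = side$Vendor %||% NA_character_,
    model = side$ScannerModel %||% NA_character_,
    software = side$SoftwareVersion %||% NA_character_)
  multiecho_dataset(mag, ph, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unclass_nifti <- function(x) {
  out <- array(as.numeric(x), dim = dim(x))
  out
}

#' Write a volume as NIfTI with geometry taken from the metadata
#'
#' Values are stored as float64 so that a read-back reproduces them
#' bit-for-bit; the affine encodes the voxel size (RAS-aligned axes).
#'
#' @param volume 3D numeric array.
#' @param meta [acquisition_meta()] supplying the voxel size.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, meta, path) {
  stopifnot(is.array(volume), length(dim(volume)) == 3)
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- meta$voxel_size
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Pipeline configuration with defaults for every stage
#'
#' @param ... Named overrides of the defaults (see the returned object for
#'   the full parameter list).
#' @return A named list of class `qsm_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    fieldmap_method = "nlfit",          # nlfit | weighted
    fit_max_iter = 30L, fit_tol = 1e-10,
    weight_scheme = "te_mag2",          # te_mag2 | mag | equal
    mask_magnitude = "first",           # first | combined
    mask_quality_factor = 1.0,
    mask_erode_voxels = 1L,
    mask_reintroduce_holes = FALSE,
    mask_closing_radius = 2L,
    bg_method = "vsharp",               # vsharp | pdf
    vsharp_radii_mm = seq(12, 1, by = -1),
    vsharp_tsvd = 0.05,
    pdf_tol = 1e-6, pdf_max_iter = 200L,
    inversion_method = "tv",            # tv | tkd
    tkd_threshold = 0.2,
    tv_lambda = 5e-4, tv_mu = 0.05,
    tv_max_iter = 100L, tv_tol = 1e-3,
    reference_region = "wholebrain",
    qc_z_threshold = 3, qc_abs_bound_ppm = 0.3,
    qc_streak_fraction = 0.01, qc_streak_ppm = 0.5,
    display_window_ppm = c(-0.2, 0.2))
  cfg <- utils::modifyList(defaults, list(...))
  unknown <- setdiff(names(list(...)), names(defaults))
  if (length(unknown)) stop("unknown config parameters: ",
                            paste(unknown, collapse = ", "))
  structure(cfg, class = "qsm_config")
}

#' Serialize / restore a pipeline configuration (YAML)
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns the
#'   restored `qsm_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}
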