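# Global Otsu threshold on a 3D volume (single threshold over the whole
# histogram; maximizes between-class variance).
otsu_threshold <- function(x, nbins = 256L) {
  r <- range(x)
  if (diff(r) == 0) stop("cannot threshold a constant volume")
  h <- tabulate(pmin(as.integer((x - r[1]) / diff(r) * nbins) + 1L, nbins),
                nbins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(nbins) - 0.5) * diff(r) / nbins
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

label_components <- function(mask) {
  array(cpp_label3d(as.logical(mask), dim(mask)), dim(mask))
}

erode_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  array(cpp_erode(as.logical(mask), dim(mask), radius), dim(mask))
}

dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  array(cpp_dilate(as.logical(mask), dim(mask), radius), dim(mask))
}

# interior cavities: background components (6-connectivity) that do not
# touch the volume border
find_holes <- function(mask) {
  bg <- label_components(!mask)
  d <- dim(mask)
  border_labels <- unique(c(
    bg[c(1, d[1]), , ], bg[, c(1, d[2]), ], bg[, , c(1, d[3])]))
  border_labels <- setdiff(border_labels, 0L)
  holes <- bg > 0 & !(bg %in% border_labels)
  array(holes, d)
}

fill_holes <- function(mask) mask | find_holes(mask)

#' Initial brain mask from a magnitude image
#'
#' Built-in method: global Otsu threshold, largest 6-connected component,
#' then morphological closing (spherical structuring element, default
#' radius 2 voxels).  Intended to mimic what a dedicated brain-extraction
#' tool produces on the first-echo or echo-combined magnitude; an external
#' tool can be plugged in via `method = "external"`, which runs
#' `external_cmd` (receiving the magnitude NIfTI path and an output path)
#' and ingests the resulting mask.
#'
#' @param magnitude Nonnegative 3D magnitude volume.
#' @param method `"threshold"` (built-in) or `"external"`.
#' @param closing_radius Closing radius in voxels for the built-in method.
#' @param external_cmd Command template for the external hook, with
#'   placeholders `{in}` and `{out}`.
#' @param meta [acquisition_meta()], required by the external hook to write
#'   the magnitude volume.
#' @return Logical mask volume.
#' @export
initial_brain_mask <- function(magnitude, method = c("threshold", "external"),
                               closing_radius = 2, external_cmd = NULL,
                               meta = NULL) {
  method <- match.arg(method)
  if (any(magnitude < 0)) stop("magnitude must be nonnegative")
  if (method == "external") {
    if (is.null(external_cmd) || is.null(meta))
      stop("external method requires external_cmd and meta")
    tin <- tempfile(fileext = ".nii.gz")
    tout <- tempfile(fileext = ".nii.gz")
    write_volume(magnitude, meta, tin)
    cmd <- gsub("{out}", tout, gsub("{in}", tin, external_cmd, fixed = TRUE),
                fixed = TRUE)
    status <- system(cmd)
    if (status != 0 || !file.exists(tout))
      stop("external brain-extraction command failed")
    m <- unclass_nifti(RNifti::readNifti(tout)) > 0.5
    return(array(m, dim(magnitude)))
  }
  if (all(magnitude == 0))
    stop("magnitude is identically zero; no brain mask can be formed")
  thr <- otsu_threshold(magnitude)
  m <- magnitude > thr
  if (!any(m))
    stop("thresholding produced an empty mask; adjust the threshold")
  lab <- label_components(m)
  sizes <- tabulate(lab[lab > 0])
  m <- lab == which.max(sizes)
  m <- erode_mask(dilate_mask(m, closing_radius), closing_radius)
  if (!any(m)) stop("brain mask is empty after morphology")
  m
}

#' Reliable-phase mask from an inverse-noise (quality) map
#'
#' Thresholds the inverse of the fit noise map at `factor` times its mean
#' over the whole FOV; the FOV-wide inverse-noise distribution is bimodal
#' (reliable tissue vs air/background), so the mean separates the modes.
#' `factor = 1.2` is a common stricter choice.
#'
#' @param noise_or_quality Either a `qsm_fieldmap` (its noise map is used)
#'   or an inverse-noise volume directly.
#' @param factor Threshold multiplier on the FOV mean (default 1).
#' @return Logical mask.
#' @export
reliable_phase_mask <- function(noise_or_quality, factor = 1.0) {
  inv <- if (inherits(noise_or_quality, "qsm_fieldmap")) {
    n <- noise_or_quality$noise
    ifelse(is.finite(n) & n > 0, 1 / n, 0)
  } else {
    noise_or_quality
  }
  if (any(!is.finite(inv))) stop("inverse-noise map must be finite")
  if (diff(range(inv)) == 0) {
    warning("constant reliability map: keeping all voxels")
    return(array(TRUE, dim(inv)))
  }
  inv >= factor * mean(inv)
}

#' Four-stage mask workflow
#'
#' Combines the initial brain mask (Mask 1) with the reliable-phase mask
#' (Mask 2): their intersection's interior cavities ("holes",
#' 6-connectivity) are filled to give the background-field-removal mask
#' (Mask 3); eroding Mask 3 gives the inversion mask (Mask 4), from which
#' the holes can optionally be re-excluded so unreliable in-brain voxels do
#' not feed the inversion.  The display mask is the eroded mask with holes
#' filled (the default display convention); the variant without holes is
#' also returned.
#'
#' @param mask1 Initial brain mask (logical).
#' @param mask2 Reliable-phase mask (logical).
#' @param erosion_voxels Erosion radius in voxels for Mask 4 (>= 0).
#' @param reintroduce_holes If `TRUE`, hole voxels are removed from Mask 4.
#' @return An object of class `qsm_maskset` with `mask1`, `mask2`, `mask3`,
#'   `mask4`, `holes`, `display` (holes filled), `display_noholes`, and
#'   `erosion_voxels`.
#' @export
finalize_masks <- function(mask1, mask2, erosion_voxels = 1L,
                           reintroduce_holes = FALSE) {
  stopifnot(all(dim(mask1) == dim(mask2)), erosion_voxels >= 0)
  intersect <- mask1 & mask2
  holes <- find_holes(intersect)
  mask3 <- intersect | holes
  if (!any(mask3)) stop("mask is empty after combining Masks 1 and 2")
  eroded <- erode_mask(mask3, erosion_voxels)
  mask4 <- if (reintroduce_holes) eroded & !holes else eroded
  structure(
    list(mask1 = mask1, mask2 = mask2, mask3 = mask3, mask4 = mask4,
         holes = holes, display = eroded, display_noholes = eroded & !holes,
         erosion_voxels = as.integer(erosion_voxels)),
    class = "qsm_maskset")
}

#' @export
print.qsm_maskset <- function(x, ...) {
  cat("<qsm_maskset> mask3:", sum(x$mask3), "voxels; mask4:", sum(x$mask4),
      "voxels; holes:", sum(x$holes),
      "; erosion:", x$erosion_voxels, "voxel(s)\n")
  invisible(x)
}
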