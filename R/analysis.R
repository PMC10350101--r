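#' Define a region of interest
#'
#' @param label Region name.
#' @param mask Logical volume.
#' @param role `"target"` or `"reference"`.
#' @return An object of class `qsm_roi`.
#' @export
roi_definition <- function(label, mask, role = c("target", "reference")) {
  role <- match.arg(role)
  structure(list(label = label, mask = mask, role = role),
            class = "qsm_roi")
}

#' Reference a susceptibility map to an internal region
#'
#' Subtracts the mean susceptibility over the region (intersected with the
#' map's validity mask) from every valid voxel.  Susceptibility is only
#' defined up to a constant, so maps must be referenced before any
#' between-subject or between-scan comparison; referencing twice to the
#' same region is a no-op.
#'
#' @param chi A `qsm_chimap`.
#' @param region A [roi_definition()], or `"wholebrain"` to use the
#'   validity mask itself.
#' @return The referenced `qsm_chimap`, with the reference recorded.
#' @export
reference_map <- function(chi, region = "wholebrain") {
  if (identical(region, "wholebrain"))
    region <- roi_definition("wholebrain", chi$valid_mask, "reference")
  sel <- region$mask & chi$valid_mask
  if (!any(sel))
    stop("reference region '", region$label,
         "' does not intersect the validity mask")
  mu <- mean(chi$chi[sel])
  chi$chi[chi$valid_mask] <- chi$chi[chi$valid_mask] - mu
  chi$reference <- list(label = region$label, mean_subtracted = mu,
                        n_voxels = sum(sel))
  chi
}

#' Re-reference a susceptibility value to a new reference region
#'
#' Given an ROI's susceptibility on an old reference scale and the new
#' reference region's mean on that same scale, the value on the new scale
#' is their difference.  E.g. an ROI at 0.010 ppm referenced to the whole
#' brain, with CSF sitting 0.002 ppm above the whole-brain mean, reads
#' 0.008 ppm when referenced to CSF.
#'
#' @param roi_value_oldref ROI value in ppm on the old reference scale.
#' @param newref_mean_oldref New reference region's mean on the same scale.
#' @return Value in ppm on the new reference scale.
#' @export
rereference_value <- function(roi_value_oldref, newref_mean_oldref) {
  stopifnot(is.finite(roi_value_oldref), is.finite(newref_mean_oldref))
  roi_value_oldref - newref_mean_oldref
}

#' ROI statistics on a referenced susceptibility map
#'
#' Per ROI: mean, standard deviation and voxel count over the intersection
#' with the validity mask only — voxels outside it (zero-filled in the
#' stored map) never enter the statistics, and their count is reported as
#' excluded.  An ROI wholly outside the validity mask yields an NA row
#' flagged in `note`, not a zero.
#'
#' @param chi A referenced `qsm_chimap` (error if unreferenced).
#' @param rois A [roi_definition()] or list of them.
#' @return A data.frame with columns `label`, `mean_ppm`, `sd_ppm`,
#'   `n_voxels`, `n_excluded`, `note`, plus attribute `reference`.
#' @export
roi_stats <- function(chi, rois) {
  if (is.null(chi$reference))
    stop("map is unreferenced; call reference_map() first (always ",
         "reference susceptibility maps to an internal region before ",
         "analysis)")
  if (inherits(rois, "qsm_roi")) rois <- list(rois)
  rows <- lapply(rois, function(r) {
    sel <- r$mask & chi$valid_mask
    n_exc <- sum(r$mask) - sum(sel)
    if (!any(sel)) {
      data.frame(label = r$label, mean_ppm = NA_real_, sd_ppm = NA_real_,
                 n_voxels = 0L, n_excluded = n_exc,
                 note = "excluded: ROI outside validity mask")
    } else {
      v <- chi$chi[sel]
      data.frame(label = r$label, mean_ppm = mean(v), sd_ppm = sd(v),
                 n_voxels = sum(sel), n_excluded = n_exc, note = "")
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "reference") <- chi$reference$label
  out
}

#' QC screening of a susceptibility map
#'
#' Returns flags, never raises: (a) any ROI mean beyond an absolute bound
#' (default 0.3 ppm, the usual display window plus margin) or, given a
#' cohort of at least 5 subject means, beyond a z-score threshold;
#' (b) a histogram spike at exactly zero inside the validity mask (a
#' masking fault leaking zero-filled voxels); (c) more than
#' `streak_fraction` of valid voxels exceeding `streak_ppm` in magnitude
#' (streaking heuristic).
#'
#' @param chi A referenced `qsm_chimap`.
#' @param rois Optional ROI list for the ROI-mean checks.
#' @param cohort_means Optional numeric vector of the same ROI's means
#'   across subjects (z-score screening needs >= 5).
#' @param z_threshold,abs_bound_ppm,streak_fraction,streak_ppm,zero_spike_fraction
#'   Screening thresholds.
#' @return A data.frame of flags with columns `check`, `flagged`, `detail`.
#' @export
qc_screen <- function(chi, rois = NULL, cohort_means = NULL,
                      z_threshold = 3, abs_bound_ppm = 0.3,
                      streak_fraction = 0.01, streak_ppm = 0.5,
                      zero_spike_fraction = 0.01) {
  flags <- list()
  add <- function(check, flagged, detail)
    flags[[length(flags) + 1]] <<- data.frame(check = check,
                                              flagged = flagged,
                                              detail = detail)
  vals <- chi$chi[chi$valid_mask]
  if (!is.null(rois)) {
    if (inherits(rois, "qsm_roi")) rois <- list(rois)
    for (r in rois) {
      sel <- r$mask & chi$valid_mask
      if (!any(sel)) next
      m <- mean(chi$chi[sel])
      out_abs <- abs(m) > abs_bound_ppm
      out_z <- FALSE
      if (!is.null(cohort_means) && length(cohort_means) >= 5) {
        z <- (m - mean(cohort_means)) / sd(cohort_means)
        out_z <- is.finite(z) && abs(z) > z_threshold
      }
      add(paste0("roi_mean:", r$label), out_abs || out_z,
          sprintf("mean %.4f ppm (bound %.2f%s)", m, abs_bound_ppm,
                  if (out_z) ", z-score outlier" else ""))
    }
  }
  zero_frac <- mean(vals == 0)
  add("zero_spike", zero_frac > zero_spike_fraction,
      sprintf("%.2f%% of valid voxels exactly zero", 100 * zero_frac))
  streak_frac <- mean(abs(vals) > streak_ppm)
  add("streaking", streak_frac > streak_fraction,
      sprintf("%.2f%% of valid voxels beyond %.2f ppm",
              100 * streak_frac, streak_ppm))
  do.call(rbind, flags)
}
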