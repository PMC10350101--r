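#' Spherical-mean-value (SMV) kernel
#'
#' Uniform averaging kernel over the discretized sphere of the given radius:
#' coefficients sum to exactly 1.  Harmonic functions are invariant under
#' this average (the mean-value property), which is what SHARP-type
#' background removal exploits.  Returned in both spatial (grid-centered)
#' and k-space (wrap-around, ready for FFT filtering) form.
#'
#' @param radius_mm Sphere radius in mm; must be at least the largest voxel
#'   dimension.
#' @param voxel_size Voxel size in mm.
#' @param grid_shape Grid shape the kernel will be applied on.
#' @return List with `spatial` (array summing to 1), `khat` (its DFT),
#'   `radius_mm`, and `n_voxels` (sphere voxel count).
#' @export
smv_kernel <- function(radius_mm, voxel_size, grid_shape) {
  if (radius_mm < max(voxel_size))
    stop("radius must be at least one voxel (", max(voxel_size), " mm)")
  ctr <- floor(grid_shape / 2) + 1
  g <- coord_grids(grid_shape, voxel_size)
  c0 <- (ctr - 0.5) * voxel_size
  inside <- (g$x - c0[1])^2 + (g$y - c0[2])^2 + (g$z - c0[3])^2 <=
    radius_mm^2
  n <- sum(inside)
  sp <- array(0, grid_shape)
  sp[inside] <- 1 / n
  khat <- fftn(ifftshift3(sp, ctr))
  list(spatial = sp, khat = khat, radius_mm = radius_mm, n_voxels = n)
}

smv_apply <- function(vol, kernel) Re(ifftn(kernel$khat * fftn(vol)))

new_tissue_field <- function(tissue_field, valid_mask, method, params) {
  tissue_field[!valid_mask] <- 0
  structure(
    list(tissue_field = tissue_field, valid_mask = valid_mask,
         method = method, params = params),
    class = "qsm_tissuefield")
}

#' @export
print.qsm_tissuefield <- function(x, ...) {
  cat("<qsm_tissuefield>", x$method, "; valid voxels:", sum(x$valid_mask),
      "\n")
  invisible(x)
}

#' V-SHARP background-field removal
#'
#' Sophisticated harmonic artifact reduction with variable spherical
#' radii: for every voxel the largest radius whose sphere fits entirely
#' inside the mask is used to apply the high-pass filter
#' `(delta - SMV)`, which annihilates harmonic (background) fields; the
#' filtering is then inverted by truncated deconvolution of
#' `(1 - SMV_khat)` at the largest radius (`tsvd_threshold`).  Voxels where
#' not even the smallest radius fits are excluded from the result
#' (approximately a one-smallest-radius erosion at the mask edge).
#'
#' @param total_field Total field in Hz.
#' @param mask3 Background-removal mask (holes filled).
#' @param radii_mm Descending radii in mm (default 12 down to 1).
#' @param tsvd_threshold Deconvolution truncation level (default 0.05).
#' @param voxel_size Voxel size in mm.
#' @return A `qsm_tissuefield` with `tissue_field` (Hz) and `valid_mask`.
#' @export
vsharp <- function(total_field, mask3, radii_mm = seq(12, 1, by = -1),
                   tsvd_threshold = 0.05, voxel_size = c(1, 1, 1)) {
  if (is.unsorted(rev(radii_mm))) stop("radii_mm must be descending")
  ok <- radii_mm >= max(voxel_size)
  if (!any(ok)) stop("no radius is at least one voxel")
  if (!all(ok)) {
    message("vsharp: dropping radii smaller than one voxel: ",
            paste(radii_mm[!ok], collapse = ", "), " mm")
    radii_mm <- radii_mm[ok]
  }
  shape <- dim(total_field)
  maskd <- array(as.numeric(mask3), shape)
  fieldm <- total_field * maskd

  filtered <- array(0, shape)
  assigned <- array(FALSE, shape)
  valid_any <- array(FALSE, shape)
  khat_largest <- NULL
  for (r in radii_mm) {
    ker <- smv_kernel(r, voxel_size, shape)
    if (is.null(khat_largest)) khat_largest <- ker$khat
    # sphere fits inside the mask wherever the SMV of the mask is ~1
    fit <- smv_apply(maskd, ker) > 1 - 1 / (2 * ker$n_voxels)
    fit <- fit & mask3
    if (!any(fit)) {
      if (r == radii_mm[1])
        warning("largest radius fits nowhere inside the mask")
      next
    }
    hp <- fieldm - smv_apply(fieldm, ker)   # (delta - SMV) field
    sel <- fit & !assigned
    filtered[sel] <- hp[sel]
    assigned <- assigned | fit
    valid_any <- valid_any | fit
  }
  if (!any(valid_any))
    stop("mask too small for the smallest SMV radius")
  # invert (delta - SMV) with the largest radius, truncated
  one_minus <- 1 - Re(khat_largest)
  inv <- ifelse(abs(one_minus) > tsvd_threshold, 1 / one_minus, 0)
  tissue <- Re(ifftn(inv * fftn(filtered * valid_any)))
  new_tissue_field(tissue, valid_any, "vsharp",
                   list(radii_mm = radii_mm,
                        tsvd_threshold = tsvd_threshold))
}

#' Projection-onto-dipole-fields (PDF) background removal
#'
#' Fits an effective susceptibility distribution supported outside the mask
#' whose dipole field best explains, in a noise-weighted least-squares
#' sense, the measured field inside the mask; the fitted background field
#' is subtracted.  Solved with conjugate gradients on the normal equations.
#'
#' @param total_field Total field in Hz.
#' @param mask3 Region-of-interest mask; sources are placed outside it.
#' @param noise_weight Nonnegative weight inside the mask (default: the
#'   binarized mask).
#' @param voxel_size Voxel size in mm.
#' @param b0_direction Main-field direction.
#' @param tol Relative-residual stopping tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 200); non-convergence returns the
#'   best iterate with a warning.
#' @return A `qsm_tissuefield` (valid mask = `mask3`).
#' @export
pdf_background <- function(total_field, mask3, noise_weight = NULL,
                           voxel_size = c(1, 1, 1),
                           b0_direction = c(0, 0, 1),
                           tol = 1e-6, max_iter = 200L) {
  if (!any(mask3)) stop("mask3 is empty")
  shape <- dim(total_field)
  if (is.null(noise_weight)) noise_weight <- array(as.numeric(mask3), shape)
  if (any(noise_weight < 0)) stop("noise_weight must be nonnegative")
  W2 <- noise_weight^2 * mask3           # weight acts inside the mask only
  Mout <- array(as.numeric(!mask3), shape)
  D <- dipole_kernel(shape, voxel_size, b0_direction)$values

  Dop <- function(x) Re(ifftn(D * fftn(x)))          # self-adjoint (D real, even)
  Aop <- function(x) Mout * Dop(W2 * Dop(Mout * x))
  b <- Mout * Dop(W2 * total_field)

  x <- array(0, shape)
  r <- b
  p <- r
  rs <- sum(r^2)
  rs0 <- rs
  converged <- rs0 == 0   # zero field: nothing to project
  it <- 0L
  for (it in seq_len(if (converged) 0L else max_iter)) {
    Ap <- Aop(p)
    alpha <- rs / sum(p * Ap)
    if (!is.finite(alpha)) break
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r^2)
    if (sqrt(rs_new / rs0) < tol) { converged <- TRUE; break }
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  if (!converged)
    warning("PDF solver did not reach tolerance ", tol, " within ",
            max_iter, " iterations; returning best iterate")
  bg <- Dop(Mout * x)
  tissue <- (total_field - bg) * mask3
  new_tissue_field(tissue, mask3, "pdf",
                   list(tol = tol, iterations = it, converged = converged))
}
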