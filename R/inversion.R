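#' Dipole kernel on the discrete Fourier grid
#'
#' The field perturbation of a susceptibility distribution is its convolution
#' with the unit magnetic dipole response; in the spatial-frequency domain
#' this convolution is multiplication with
#' \deqn{D(k) = 1/3 - (k \cdot \hat b)^2 / |k|^2,}
#' the continuous-kernel convention.  `D` vanishes on the cone at the magic
#' angle (about 54.7 degrees) from the main-field direction, which is what
#' makes dipole inversion ill-posed.  The k = 0 value is a free constant
#' (susceptibility maps are relative); it defaults to 0.
#'
#' @param grid_shape Integer length-3 array shape.
#' @param voxel_size Voxel size in mm (length 3).
#' @param b0_direction Unit vector of the main field in image axes; oblique
#'   directions are supported.
#' @param dc_value Value assigned at k = 0 (default 0).
#' @return An object of class `qsm_dipole` with the kernel array in `values`.
#' @export
dipole_kernel <- function(grid_shape, voxel_size = c(1, 1, 1),
                          b0_direction = c(0, 0, 1), dc_value = 0) {
  b0 <- as.numeric(b0_direction)
  nb <- sqrt(sum(b0^2))
  if (nb < 1e-12) stop("b0_direction must be nonzero")
  b0 <- b0 / nb
  g <- kspace_grids(grid_shape, voxel_size)
  k2 <- g$kx^2 + g$ky^2 + g$kz^2
  kb <- g$kx * b0[1] + g$ky * b0[2] + g$kz * b0[3]
  D <- 1 / 3 - kb^2 / k2
  D[k2 == 0] <- dc_value
  structure(
    list(values = D, b0_direction = b0, dc_value = dc_value,
         grid_shape = as.integer(grid_shape),
         voxel_size = as.numeric(voxel_size)),
    class = "qsm_dipole")
}

#' Angular profile of the dipole kernel and its magic-angle root
#'
#' `dipole_profile(theta_deg)` evaluates the kernel value for a spatial
#' frequency at angle `theta_deg` from the main-field direction
#' (`1/3 - cos^2(theta)`); `magic_angle()` root-finds that profile on
#' (0, 90) degrees, returning the angle at which the kernel vanishes.
#'
#' @param theta_deg Angle(s) from the main-field direction in degrees.
#' @return `dipole_profile`: kernel value(s); `magic_angle`: the root in
#'   degrees (about 54.7).
#' @export
dipole_profile <- function(theta_deg) {
  1 / 3 - cos(theta_deg * pi / 180)^2
}

#' @rdname dipole_profile
#' @export
magic_angle <- function() {
  stats::uniroot(dipole_profile, c(1, 89), tol = 1e-12)$root
}

# field (Hz) <-> dimensionless ppm at a given B0
hz_to_ppm <- function(field_hz, b0) field_hz / (GAMMA_BAR_HZ_T * b0) * 1e6
ppm_to_hz <- function(field_ppm, b0) field_ppm * GAMMA_BAR_HZ_T * b0 * 1e-6

#' Convert a phase-type quantity in radians to ppm
#'
#' Applies the scaling \eqn{10^6 / (\gamma_{rad} B_0 \Delta TE)} with
#' \eqn{\gamma_{rad} = 2\pi \cdot 42.577478} MHz/T, i.e. the conversion of a
#' field map expressed as phase accrued over one echo spacing into parts per
#' million.
#'
#' @param value_rad Value(s) in radians.
#' @param b0 Field strength in tesla (> 0).
#' @param delta_te Echo spacing in seconds (> 0).
#' @return Value(s) in ppm.
#' @export
scale_to_ppm <- function(value_rad, b0, delta_te) {
  if (!(b0 > 0)) stop("b0 must be > 0")
  if (!(delta_te > 0)) stop("delta_te must be > 0")
  value_rad * 1e6 / (2 * pi * GAMMA_BAR_HZ_T * b0 * delta_te)
}

new_chi_map <- function(chi, valid_mask, method, params) {
  structure(
    list(chi = chi, valid_mask = valid_mask, reference = NULL,
         method = method, params = params),
    class = "qsm_chimap")
}

#' @export
print.qsm_chimap <- function(x, ...) {
  cat("<qsm_chimap>", x$method, "inversion, grid",
      paste(dim(x$chi), collapse = "x"), "\n")
  if (!is.null(x$reference))
    cat("referenced to:", x$reference$label,
        sprintf("(mean %.4g ppm subtracted)\n", x$reference$mean_subtracted))
  else cat("unreferenced\n")
  invisible(x)
}

#' Thresholded k-space division (TKD) dipole inversion
#'
#' Direct deconvolution baseline: divide the field's spectrum by the dipole
#' kernel, replacing kernel values smaller in magnitude than `threshold` by
#' `sign(D) * threshold` (sign of zero taken as +) to cap noise
#' amplification near the magic-angle cone.
#'
#' @param tissue_field Tissue field in Hz (3D array).
#' @param kernel A [dipole_kernel()] on the same grid.
#' @param threshold Truncation level in (0, 2/3); default 0.2.
#' @param meta [acquisition_meta()] (provides B0 for the Hz-to-ppm scaling).
#' @param valid_mask Binary validity mask; output is zero outside it.
#' @return A `qsm_chimap` with `chi` in ppm.
#' @export
tkd_invert <- function(tissue_field, kernel, threshold = 0.2, meta,
                       valid_mask = NULL) {
  stopifnot(threshold > 0, threshold < 2 / 3)
  if (is.null(valid_mask)) valid_mask <- array(TRUE, dim(tissue_field))
  D <- kernel$values
  s <- ifelse(D >= 0, 1, -1)
  Dp <- ifelse(abs(D) >= threshold, D, s * threshold)
  field_ppm <- hz_to_ppm(tissue_field, meta$field_strength)
  chi <- Re(ifftn(fftn(field_ppm) / Dp))
  chi[!valid_mask] <- 0
  new_chi_map(chi, valid_mask, "tkd",
              list(threshold = threshold, dc_value = kernel$dc_value))
}

# periodic forward-difference operators in k-space (one per axis)
grad_operators_k <- function(shape) {
  lapply(1:3, function(a) {
    n <- shape[a]
    e <- exp(2i * pi * (0:(n - 1)) / n) - 1
    arr <- array(e[switch(a,
      rep(1:n, times = shape[2] * shape[3]),
      rep(rep(1:n, each = shape[1]), times = shape[3]),
      rep(1:n, each = shape[1] * shape[2]))], dim = shape)
    arr
  })
}

tv_norm_iso <- function(gx, gy, gz) sum(sqrt(gx^2 + gy^2 + gz^2))

#' Total-variation regularized dipole inversion
#'
#' Solves
#' \deqn{\hat\chi = \arg\min_\chi \| w (\Delta B_t - d * \chi) \|_2^2
#'   + \lambda\, TV(\chi)}
#' by alternating-direction splitting with auxiliary variables for the
#' spatial gradient (isotropic TV, gradient-consistency weight
#' `mu_consistency`) and for the dipole-convolved field (unit consistency
#' weight), so every subproblem is closed-form.  The field is converted to
#' ppm before inversion so the default `lambda_reg` operates on the
#' conventional ppm scale.  The solver is deterministic.
#'
#' @param tissue_field Tissue field in Hz.
#' @param kernel A [dipole_kernel()] on the same grid.
#' @param weight_w Nonnegative data-fidelity weight, zero outside
#'   `valid_mask`; default: the binarized valid mask.  A noise-derived map
#'   is normalized to its median inside the mask and clipped at its 99th
#'   percentile by [fidelity_weight()].
#' @param lambda_reg Gradient-L1 penalty (default 5e-4).
#' @param mu_consistency Gradient consistency weight (default 0.05).
#' @param max_iter Outer iteration cap (default 100).
#' @param tol Stop when the relative update of chi falls below this
#'   (default 1e-3).
#' @param meta [acquisition_meta()].
#' @param valid_mask Binary validity mask.
#' @return A `qsm_chimap` with `chi` in ppm, the lambda record in `params`,
#'   and the per-iteration objective in `params$objective`.
#' @export
tv_invert <- function(tissue_field, kernel, weight_w = NULL,
                      lambda_reg = 5e-4, mu_consistency = 0.05,
                      max_iter = 100L, tol = 1e-3, meta,
                      valid_mask = NULL) {
  stopifnot(lambda_reg > 0, mu_consistency > 0)
  shape <- dim(tissue_field)
  if (is.null(valid_mask)) valid_mask <- array(TRUE, shape)
  if (is.null(weight_w)) weight_w <- array(as.numeric(valid_mask), shape)
  if (any(weight_w < 0)) stop("weight_w must be nonnegative")
  b <- hz_to_ppm(tissue_field, meta$field_strength) * valid_mask
  D <- kernel$values
  E <- grad_operators_k(shape)
  mu1 <- mu_consistency   # gradient split
  mu2 <- 1                # fidelity split
  W2 <- weight_w^2
  denom <- mu2 * abs(D)^2 + mu1 * (abs(E[[1]])^2 + abs(E[[2]])^2 + abs(E[[3]])^2)
  denom[denom == 0] <- mu2 * 1e-12 + mu1  # k=0 bin: any finite value, numerator is 0 there

  Fx <- fftn(array(0, shape))
  zd <- array(0, shape); sd_ <- array(0, shape)
  zg <- lapply(1:3, function(i) array(0, shape))
  sg <- lapply(1:3, function(i) array(0, shape))
  obj <- numeric(0)
  x_prev <- array(0, shape)
  n_increase <- 0

  for (it in seq_len(max_iter)) {
    # x-update (diagonal in k-space)
    num <- mu2 * Conj(D) * fftn(zd - sd_)
    for (i in 1:3) num <- num + mu1 * Conj(E[[i]]) * fftn(zg[[i]] - sg[[i]])
    Fx <- num / denom
    x <- Re(ifftn(Fx))
    Dx <- Re(ifftn(D * Fx))
    gx <- lapply(1:3, function(i) Re(ifftn(E[[i]] * Fx)))

    # isotropic shrinkage of the gradient split
    vx <- lapply(1:3, function(i) gx[[i]] + sg[[i]])
    mag <- sqrt(vx[[1]]^2 + vx[[2]]^2 + vx[[3]]^2)
    shrink <- pmax(0, 1 - (lambda_reg / mu1) / pmax(mag, 1e-30))
    zg <- lapply(1:3, function(i) vx[[i]] * shrink)

    # weighted fidelity split
    zd <- (W2 * b + mu2 * (Dx + sd_)) / (W2 + mu2)

    # dual updates
    for (i in 1:3) sg[[i]] <- sg[[i]] + gx[[i]] - zg[[i]]
    sd_ <- sd_ + Dx - zd

    o <- sum((weight_w * (b - Dx))^2) +
      lambda_reg * tv_norm_iso(gx[[1]], gx[[2]], gx[[3]])
    if (length(obj) && o > tail(obj, 1) * (1 + 1e-3) + 1e-12) {
      n_increase <- n_increase + 1
      # transient oscillation is normal for splitting methods; call it
      # divergence only when the objective has also left its running
      # minimum far behind
      if (n_increase >= 5 && o > 1.5 * min(obj))
        stop("tv_invert diverged: objective increased for 5 consecutive ",
             "iterations (last = ", signif(o, 6), ")")
    } else n_increase <- 0
    obj <- c(obj, o)

    rel <- sqrt(sum((x - x_prev)^2)) / max(sqrt(sum(x^2)), 1e-30)
    x_prev <- x
    if (it > 1 && rel < tol) break
  }
  chi <- x
  chi[!valid_mask] <- 0
  new_chi_map(chi, valid_mask, "tv",
              list(lambda = lambda_reg, mu_consistency = mu_consistency,
                   iterations = length(obj), objective = obj,
                   converged = rel < tol))
}

#' Default data-fidelity weight from a noise map
#'
#' Inverse-noise weighting normalized to its median inside the mask and
#' clipped at the 99th percentile (extreme reliabilities should not dominate
#' the fidelity term); zero outside the mask.
#'
#' @param noise Per-voxel field-uncertainty map (larger = less reliable).
#' @param valid_mask Binary mask.
#' @return Weight array.
#' @export
fidelity_weight <- function(noise, valid_mask) {
  inv <- 1 / pmax(noise, .Machine$double.eps)
  inv[!valid_mask] <- 0
  vals <- inv[valid_mask]
  cap <- stats::quantile(vals, 0.99, names = FALSE)
  inv <- pmin(inv, cap)
  md <- stats::median(inv[valid_mask])
  if (md > 0) inv <- inv / md
  array(inv, dim(noise))
}

#' L-curve corner selection of the regularization parameter
#'
#' `lcurve_corner()` locates the maximum-curvature point of a log-log
#' L-curve given residual and regularizer norms; `lcurve_select()` builds
#' that curve by running [tv_invert()] over a lambda grid.
#'
#' @param residual_norms,reg_norms Positive numerics, one per lambda.
#' @param lambdas Positive increasing lambda grid (>= 3 values; >= 4 for
#'   `lcurve_select`).
#' @return A list with `lambda` (the selection), `index`, and `table`, a
#'   data.frame of lambda, residual norm, regularizer norm and curvature.
#' @export
lcurve_corner <- function(residual_norms, reg_norms, lambdas) {
  stopifnot(length(residual_norms) == length(lambdas),
            length(reg_norms) == length(lambdas), length(lambdas) >= 3)
  if (any(diff(residual_norms) < 0))
    warning("residual norms are not monotonically increasing in lambda")
  xi <- log(residual_norms)
  eta <- log(reg_norms)
  n <- length(lambdas)
  kappa <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    # three-point derivatives parameterized by log-lambda
    t1 <- log(lambdas[i]) - log(lambdas[i - 1])
    t2 <- log(lambdas[i + 1]) - log(lambdas[i])
    xp <- (xi[i + 1] - xi[i - 1]) / (t1 + t2)
    yp <- (eta[i + 1] - eta[i - 1]) / (t1 + t2)
    xpp <- 2 * (t1 * xi[i + 1] - (t1 + t2) * xi[i] + t2 * xi[i - 1]) /
      (t1 * t2 * (t1 + t2))
    ypp <- 2 * (t1 * eta[i + 1] - (t1 + t2) * eta[i] + t2 * eta[i - 1]) /
      (t1 * t2 * (t1 + t2))
    kappa[i] <- (xp * ypp - yp * xpp) / (xp^2 + yp^2)^(3 / 2)
  }
  if (n == 3)
    warning("only one interior grid point; returning the middle lambda")
  idx <- which.max(kappa)
  list(lambda = lambdas[idx], index = idx,
       table = data.frame(lambda = lambdas, residual = residual_norms,
                          regularizer = reg_norms, curvature = kappa))
}

#' @rdname lcurve_corner
#' @param tissue_field,kernel,weight_w,meta,valid_mask,... Passed to
#'   [tv_invert()].
#' @param lambda_grid Positive sorted lambda grid (>= 4 values).
#' @export
lcurve_select <- function(tissue_field, kernel, weight_w = NULL,
                          lambda_grid, meta, valid_mask = NULL, ...) {
  stopifnot(length(lambda_grid) >= 4, all(lambda_grid > 0),
            !is.unsorted(lambda_grid))
  res <- reg <- numeric(length(lambda_grid))
  maps <- vector("list", length(lambda_grid))
  for (i in seq_along(lambda_grid)) {
    m <- tv_invert(tissue_field, kernel, weight_w = weight_w,
                   lambda_reg = lambda_grid[i], meta = meta,
                   valid_mask = valid_mask, ...)
    maps[[i]] <- m
    b <- hz_to_ppm(tissue_field, meta$field_strength)
    D <- kernel$values
    Dx <- Re(ifftn(D * fftn(m$chi)))
    w <- if (is.null(weight_w)) {
      if (is.null(valid_mask)) array(1, dim(tissue_field))
      else array(as.numeric(valid_mask), dim(tissue_field))
    } else weight_w
    res[i] <- sqrt(sum((w * (b - Dx))^2))
    E <- grad_operators_k(dim(m$chi))
    g <- lapply(E, function(e) Re(ifftn(e * fftn(m$chi))))
    reg[i] <- tv_norm_iso(g[[1]], g[[2]], g[[3]])
  }
  out <- lcurve_corner(res, reg, lambda_grid)
  out$maps <- maps
  out
}
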