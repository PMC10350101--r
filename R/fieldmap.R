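new_fieldmap <- function(field, phi0, noise, quality, method, params) {
  structure(
    list(field = field, phi0 = phi0, noise = noise, quality = quality,
         method = method, params = params),
    class = "qsm_fieldmap")
}

#' @export
print.qsm_fieldmap <- function(x, ...) {
  cat("<qsm_fieldmap>", x$method, "estimate, grid",
      paste(dim(x$field), collapse = "x"), "\n")
  invisible(x)
}

#' Nonlinear complex multi-echo field fitting
#'
#' Least-squares fit, per voxel, of the complex model
#' `M(TE) * exp(i * (2*pi*f*TE + phi0))` to the measured complex signal
#' across echoes (magnitude taken from the data), requiring three or more
#' echoes.  Initialization uses the wrapped temporal phase differences
#' between consecutive echoes; Gauss-Newton refinement then solves for the
#' field `f` (Hz) and the echo-time-zero offset `phi0` jointly.  For uniform
#' echo spacing the returned field is the principal value within
#' `+/- 1/(2 * dTE)`; spatially wrapped regions may still require
#' [unwrap_spatial()] afterwards.
#'
#' The returned `noise` map is the fit-derived standard error of `f`
#' (residual-scaled inverse precision); `quality` is the inverse noise,
#' min-max normalized into `[0, 1]` over the FOV.  Voxels with all-zero
#' magnitude get quality 0.
#'
#' @param data A [multiecho_dataset()] with >= 3 echoes.
#' @param max_iter,tol Gauss-Newton iteration cap and relative tolerance.
#' @return A `qsm_fieldmap` with elements `field` (Hz), `phi0` (rad),
#'   `noise`, `quality`.
#' @export
fit_complex_multiecho <- function(data, max_iter = 30L, tol = 1e-10) {
  ne <- length(data$phase)
  if (ne < 3)
    stop("fit_complex_multiecho requires >= 3 echoes; ",
         "use combine_weighted_average() for fewer")
  shape <- dim(data$phase[[1]])
  te <- data$meta$te
  nv <- prod(shape)
  # complex signal matrix, voxels x echoes; undo the vendor sign so the
  # fitted field has paramagnetic-positive polarity
  S <- matrix(0i, nv, ne)
  M <- matrix(0, nv, ne)
  for (e in seq_len(ne)) {
    M[, e] <- as.numeric(data$magnitude[[e]])
    S[, e] <- M[, e] * exp(1i * data$meta$phase_sign *
                             as.numeric(data$phase[[e]]))
  }
  zero_vox <- rowSums(M) == 0

  # init: magnitude-weighted mean of pairwise temporal phase differences
  num <- rep(0, nv); den <- rep(0, nv)
  for (e in seq_len(ne - 1)) {
    d <- Arg(S[, e + 1] * Conj(S[, e]))
    w <- M[, e + 1] * M[, e]
    num <- num + w * d / (te[e + 1] - te[e])
    den <- den + w
  }
  f <- ifelse(den > 0, num / den / (2 * pi), 0)
  phi0 <- Arg(S[, 1] * exp(-2i * pi * f * te[1]))
  phi0[zero_vox] <- 0

  # Gauss-Newton on (f, phi0), vectorized over voxels
  for (it in seq_len(max_iter)) {
    model_phase <- outer(2 * pi * f, te) + phi0
    Shat <- M * exp(1i * model_phase)
    R <- S - Shat
    # normal-equation entries for columns (2*pi*TE*i*Shat, i*Shat)
    m2 <- M^2
    A <- drop(m2 %*% (2 * pi * te)^2)
    B <- drop(m2 %*% (2 * pi * te))
    C <- rowSums(m2)
    cr <- Im(Conj(Shat) * R)
    g1 <- drop(cr %*% (2 * pi * te))
    g2 <- rowSums(cr)
    det <- A * C - B^2
    ok <- det > .Machine$double.eps
    df <- ifelse(ok, (C * g1 - B * g2) / det, 0)
    dphi <- ifelse(ok, (A * g2 - B * g1) / det, 0)
    f <- f + df
    phi0 <- phi0 + dphi
    if (max(abs(df) * max(te), abs(dphi)) < tol) break
  }
  if (has_uniform_spacing(te) && ne >= 2) {
    # principal value in +/- 1/(2 dTE); phi0 absorbs the aliased turns so
    # that the model still reproduces the measured phases modulo 2*pi
    dte <- te[2] - te[1]
    k <- round(f * dte)
    f <- f - k / dte
    phi0 <- phi0 + 2 * pi * k * te[1] / dte
  }
  phi0 <- wrap_phase(phi0)
  f[zero_vox] <- 0
  phi0[zero_vox] <- 0

  model_phase <- outer(2 * pi * f, te) + phi0
  Shat <- M * exp(1i * model_phase)
  res2 <- rowSums(Mod(S - Shat)^2)
  dof <- max(2 * ne - 3, 1)
  sigma2 <- pmax(res2 / dof, .Machine$double.eps)
  m2 <- M^2
  A <- drop(m2 %*% (2 * pi * te)^2)
  B <- drop(m2 %*% (2 * pi * te))
  C <- rowSums(m2)
  prec_f <- pmax(A - ifelse(C > 0, B^2 / C, 0), 0)
  noise <- ifelse(prec_f > 0, sqrt(sigma2 / prec_f), Inf)
  invnoise <- ifelse(is.finite(noise), 1 / noise, 0)
  qrange <- range(invnoise)
  quality <- if (diff(qrange) > 0) (invnoise - qrange[1]) / diff(qrange)
  else rep(1, nv)
  quality[zero_vox] <- 0

  new_fieldmap(array(f, shape), array(phi0, shape), array(noise, shape),
               array(quality, shape), "nlfit",
               list(iterations = it, n_echoes = ne))
}

#' Exact spatial phase unwrapping by quality-guided region growing
#'
#' Path-based unwrapping: each 6-connected component of the mask is grown
#' from its highest-quality voxel in descending quality order (deterministic
#' voxel-index tie-break), and every voxel is offset by the integer multiple
#' of `2*pi` that best matches its already-unwrapped neighbour.  The output
#' therefore differs from the input by exact multiples of `2*pi` voxelwise
#' ("exact" unwrapping).  Disconnected mask components are internally
#' consistent but carry unconstrained relative offsets; their count is
#' returned and a message emitted when more than one is present.
#'
#' @param wrapped Phase volume in radians within `[-pi, pi)`.
#' @param quality Per-voxel reliability (larger = earlier growth).
#' @param mask Logical volume; unwrapping is defined only inside it.
#' @return Unwrapped volume (NA outside the mask) with attribute
#'   `n_components`.
#' @export
unwrap_spatial <- function(wrapped, quality, mask) {
  stopifnot(all(dim(wrapped) == dim(mask)),
            all(dim(quality) == dim(mask)))
  if (!any(mask)) stop("mask is empty")
  res <- cpp_unwrap_region_grow(as.numeric(wrapped), as.numeric(quality),
                                as.logical(mask), dim(wrapped))
  if (res$n_components > 1)
    message("unwrap_spatial: ", res$n_components, " disconnected mask ",
            "components; inter-component offsets are unconstrained")
  out <- array(res$unwrapped, dim(wrapped))
  attr(out, "n_components") <- res$n_components
  out
}

#' Weighted multi-echo averaging of the field
#'
#' Estimates the field as the weighted average of per-echo phase slopes
#' after removing the TE = 0 offset:
#' `f = sum(w_e * (phi_e - phi0) / (2*pi*TE_e)) / sum(w_e)` with default
#' weights `w_e = TE_e * M_e^2` (inverse phase-variance weighting under
#' high-SNR complex Gaussian noise).  When per-echo unwrapped phases are not
#' supplied, template unwrapping is used: the first two echoes are unwrapped
#' spatially, `phi0` is obtained by linear extrapolation to TE = 0, later
#' echoes are predicted by linear TE scaling and their residual `2*pi` jumps
#' resolved per voxel.
#'
#' @param data A [multiecho_dataset()] with >= 2 echoes.
#' @param unwrapped_phases Optional list of per-echo unwrapped phase volumes
#'   (vendor sign already removed).
#' @param phi0 Optional TE = 0 phase-offset volume in radians.
#' @param weights `"te_mag2"` (default), `"mag"`, or `"equal"`.
#' @param mask Logical volume for the template unwrapping (default: voxels
#'   with positive first-echo magnitude).
#' @return A `qsm_fieldmap`.
#' @export
combine_weighted_average <- function(data, unwrapped_phases = NULL,
                                     phi0 = NULL,
                                     weights = c("te_mag2", "mag", "equal"),
                                     mask = NULL) {
  weights <- match.arg(weights)
  ne <- length(data$phase)
  if (ne < 2) stop("combine_weighted_average requires >= 2 echoes")
  te <- data$meta$te
  shape <- dim(data$phase[[1]])
  sgn <- data$meta$phase_sign
  if (is.null(mask)) mask <- data$magnitude[[1]] > 0
  if (is.null(unwrapped_phases)) {
    q <- data$magnitude[[1]]
    u1 <- unwrap_spatial(wrap_phase(data$phase[[1]] * sgn), q, mask)
    u2 <- unwrap_spatial(wrap_phase(data$phase[[2]] * sgn), q, mask)
    # align echo-2 globally with the echo-1 slope prediction (the two
    # independent unwraps may differ by a constant 2*pi multiple)
    pred2 <- u1 * te[2] / te[1]
    off <- 2 * pi * round(stats::median((pred2 - u2)[mask]) / (2 * pi))
    u2 <- u2 + off
    if (is.null(phi0)) phi0 <- u1 - te[1] * (u2 - u1) / (te[2] - te[1])
    unwrapped_phases <- vector("list", ne)
    unwrapped_phases[[1]] <- u1
    unwrapped_phases[[2]] <- u2
    if (ne > 2) {
      slope <- (u1 - phi0) / te[1]
      for (e in 3:ne) {
        pred <- phi0 + slope * te[e]
        w <- wrap_phase(data$phase[[e]] * sgn)
        unwrapped_phases[[e]] <- w + 2 * pi * round((pred - w) / (2 * pi))
      }
    }
  } else if (is.null(phi0)) {
    u1 <- unwrapped_phases[[1]]; u2 <- unwrapped_phases[[2]]
    phi0 <- u1 - te[1] * (u2 - u1) / (te[2] - te[1])
  }
  num <- array(0, shape); den <- array(0, shape)
  for (e in seq_len(ne)) {
    w <- switch(weights,
      te_mag2 = te[e] * data$magnitude[[e]]^2,
      mag = data$magnitude[[e]],
      equal = array(1, shape))
    num <- num + w * (unwrapped_phases[[e]] - phi0) / (2 * pi * te[e])
    den <- den + w
  }
  f <- array(0, shape)
  pos <- den > 0
  f[pos] <- num[pos] / den[pos]
  f[!mask] <- 0
  noise <- array(Inf, shape)
  noise[pos] <- 1 / sqrt(den[pos])
  invn <- ifelse(is.finite(noise), 1 / noise, 0)
  rg <- range(invn)
  quality <- if (diff(rg) > 0) (invn - rg[1]) / diff(rg) else array(1, shape)
  new_fieldmap(f, wrap_phase(phi0), noise, array(quality, shape),
               "weighted",
               list(weights = weights, n_echoes = ne))
}
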