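#' Specify a geometric susceptibility phantom
#'
#' A phantom is a set of geometric primitives (spheres, axis-aligned
#' cylinders and cuboids) carrying susceptibility (ppm), T2* (s) and
#' proton-density magnitude, split into in-brain `primitives` and
#' `background_sources` outside the brain region, plus a smooth TE = 0
#' phase-offset field and a magnitude SNR.  Everything downstream of the
#' scanner — total field, tissue/background decomposition, phase wraps,
#' noise — can then be computed with known ground truth.
#'
#' @param shape Grid shape (length 3).
#' @param voxel_size Voxel size in mm.
#' @param primitives List of primitives (see [phantom_sphere()]); these are
#'   the in-brain susceptibility sources.
#' @param background_sources Primitives outside the brain region (e.g. an
#'   air-filled sinus-like sphere, susceptibility offset about 9 ppm from
#'   tissue).
#' @param brain_region A single primitive defining the true brain mask.
#' @param phi0_coef Named numeric vector of low-order polynomial
#'   coefficients for the TE = 0 phase offset, in radians over normalized
#'   coordinates in `[-1, 1]`: names among `1, x, y, z, x2, y2, z2, xy, xz,
#'   yz`.
#' @param snr Magnitude SNR at the first echo inside the brain (> 0).
#' @param seed Integer RNG seed used by [simulate_multiecho()].
#' @return An object of class `qsm_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), voxel_size = c(1, 1, 1),
                         primitives = list(), background_sources = list(),
                         brain_region, phi0_coef = c("1" = 0), snr = 50,
                         seed = 1L) {
  if (!(snr > 0)) stop("snr must be > 0")
  chis <- vapply(c(primitives, background_sources),
                 function(p) p$chi, numeric(1))
  if (length(chis) && any(!is.finite(chis)))
    stop("primitive chi values must be finite")
  structure(
    list(shape = as.integer(shape), voxel_size = as.numeric(voxel_size),
         primitives = primitives, background_sources = background_sources,
         brain_region = brain_region, phi0_coef = phi0_coef,
         snr = snr, seed = as.integer(seed)),
    class = "qsm_phantom_spec")
}

#' Phantom primitives
#'
#' Constructors for the geometric primitives a phantom is built from.
#' Coordinates and dimensions are in mm; the grid origin is at the corner,
#' voxel centers at `(i - 0.5) * voxel_size`.
#'
#' @param center Length-3 center in mm.
#' @param radius Sphere/cylinder radius in mm.
#' @param chi Susceptibility in ppm.
#' @param t2star T2* in seconds.
#' @param magnitude Proton-density magnitude (arbitrary units).
#' @return A primitive list usable in [phantom_spec()].
#' @export
phantom_sphere <- function(center, radius, chi = 0, t2star = 0.05,
                           magnitude = 1) {
  list(shape = "sphere", center = center, dimensions = radius, chi = chi,
       t2star = t2star, magnitude = magnitude)
}

#' @rdname phantom_sphere
#' @param length_mm Cylinder length along `axis`.
#' @param axis Cylinder axis: 1, 2 or 3.
#' @export
phantom_cylinder <- function(center, radius, length_mm, axis = 3, chi = 0,
                             t2star = 0.05, magnitude = 1) {
  list(shape = "cylinder", center = center,
       dimensions = c(radius, length_mm, axis), chi = chi,
       t2star = t2star, magnitude = magnitude)
}

#' @rdname phantom_sphere
#' @param size Length-3 edge lengths in mm.
#' @export
phantom_cuboid <- function(center, size, chi = 0, t2star = 0.05,
                           magnitude = 1) {
  list(shape = "cuboid", center = center, dimensions = size, chi = chi,
       t2star = t2star, magnitude = magnitude)
}

#' Built-in phantom presets
#'
#' The `"default"` scene is a 64^3 grid at 2 mm (128 mm field of view,
#' i.e. head-scale so that the standard background-removal radii are small
#' against the brain): a brain sphere of radius 40 mm (chi = 0) containing
#' two 10 mm spheres at +0.1 and -0.1 ppm, a dim tissue shell around the
#' brain, and an external air sphere with a 9 ppm susceptibility offset
#' (the approximate brain/air contrast) that creates a realistic background
#' field.  SNR defaults to 50.
#'
#' @param name Preset name (currently `"default"`).
#' @param snr,seed Override the preset SNR / seed.
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(name = "default", snr = 50, seed = 1L) {
  name <- match.arg(name)
  ctr <- c(64, 64, 64)
  brain <- phantom_sphere(ctr, 40, chi = 0, t2star = 0.05, magnitude = 1)
  shell <- phantom_sphere(ctr, 46, chi = 0, t2star = 0.01, magnitude = 0.15)
  para <- phantom_sphere(ctr + c(16, 0, 0), 10, chi = 0.1, t2star = 0.03,
                         magnitude = 0.9)
  dia <- phantom_sphere(ctr + c(-16, 0, 0), 10, chi = -0.1, t2star = 0.06,
                        magnitude = 0.95)
  air <- phantom_sphere(ctr + c(0, 0, 52), 8, chi = 9, t2star = 1e-4,
                        magnitude = 0)
  phantom_spec(
    shape = c(64, 64, 64), voxel_size = c(2, 2, 2),
    primitives = list(shell, brain, para, dia),
    background_sources = list(air),
    brain_region = brain,
    phi0_coef = c("1" = 0.3, x = 0.4, y = -0.25, z2 = 0.35),
    snr = snr, seed = seed)
}

#' Masks of the preset's inner target spheres
#'
#' Voxel masks (optionally eroded) of the paramagnetic and diamagnetic
#' target spheres of [phantom_preset()], for ROI analysis against ground
#' truth.
#'
#' @param spec The preset [phantom_spec()].
#' @param erode_mm Radial margin in mm removed from each sphere (default 2).
#' @return Named list of two logical arrays, `para` and `dia`.
#' @export
phantom_target_masks <- function(spec = phantom_preset(), erode_mm = 2) {
  g <- coord_grids(spec$shape, spec$voxel_size)
  prims <- spec$primitives
  chis <- vapply(prims, function(p) p$chi, numeric(1))
  para <- prims[[which(chis > 0)[1]]]
  dia <- prims[[which(chis < 0)[1]]]
  shrink <- function(p) {
    q <- p
    q$dimensions <- p$dimensions - erode_mm
    primitive_mask(q, g)
  }
  list(para = shrink(para), dia = shrink(dia))
}

# voxel-center coordinate arrays in mm
coord_grids <- function(shape, voxel_size) {
  cx <- (seq_len(shape[1]) - 0.5) * voxel_size[1]
  cy <- (seq_len(shape[2]) - 0.5) * voxel_size[2]
  cz <- (seq_len(shape[3]) - 0.5) * voxel_size[3]
  list(x = array(cx, dim = shape),
       y = array(rep(cy, each = shape[1]), dim = shape),
       z = array(rep(cz, each = shape[1] * shape[2]), dim = shape))
}

primitive_mask <- function(prim, g) {
  c0 <- prim$center
  switch(prim$shape,
    sphere = (g$x - c0[1])^2 + (g$y - c0[2])^2 + (g$z - c0[3])^2 <=
      prim$dimensions[1]^2,
    cylinder = {
      r <- prim$dimensions[1]; len <- prim$dimensions[2]
      ax <- prim$dimensions[3]
      co <- list(g$x - c0[1], g$y - c0[2], g$z - c0[3])
      axial <- co[[ax]]
      rad2 <- Reduce(`+`, lapply(setdiff(1:3, ax), function(i) co[[i]]^2))
      rad2 <= r^2 & abs(axial) <= len / 2
    },
    cuboid = abs(g$x - c0[1]) <= prim$dimensions[1] / 2 &
      abs(g$y - c0[2]) <= prim$dimensions[2] / 2 &
      abs(g$z - c0[3]) <= prim$dimensions[3] / 2,
    stop("unknown primitive shape: ", prim$shape))
}

#' Voxelize a phantom's susceptibility scene
#'
#' Rasterizes the in-brain primitives followed by the background sources
#' onto the grid; where primitives overlap, later ones overwrite earlier
#' ones.  A label volume records which primitive each voxel came from
#' (0 = none).
#'
#' @param spec A [phantom_spec()].
#' @param which One of `"all"`, `"tissue"` (in-brain primitives only) or
#'   `"background"`.
#' @return List with `chi` (ppm), `label` (integer), `t2star` (s),
#'   `magnitude`, and `brain_mask` (logical).
#' @export
build_chi_volume <- function(spec, which = c("all", "tissue", "background")) {
  which <- match.arg(which)
  g <- coord_grids(spec$shape, spec$voxel_size)
  prims <- switch(which,
    all = c(spec$primitives, spec$background_sources),
    tissue = spec$primitives,
    background = spec$background_sources)
  chi <- array(0, spec$shape)
  lab <- array(0L, spec$shape)
  t2s <- array(Inf, spec$shape)
  m0 <- array(0, spec$shape)
  for (i in seq_along(prims)) {
    m <- primitive_mask(prims[[i]], g)
    if (!any(m)) {
      warning("primitive ", i, " lies entirely outside the grid")
      next
    }
    chi[m] <- prims[[i]]$chi
    lab[m] <- i
    t2s[m] <- prims[[i]]$t2star
    m0[m] <- prims[[i]]$magnitude
  }
  brain <- primitive_mask(spec$brain_region, g)
  if (!any(brain)) stop("brain_region is empty on this grid")
  list(chi = chi, label = lab, t2star = t2s, magnitude = m0,
       brain_mask = brain)
}

#' Forward field of a susceptibility distribution
#'
#' Convolves the susceptibility volume with the unit dipole response by
#' k-space multiplication, after zero-padding each axis (factor 2 by
#' default) to suppress wrap-around of the long-range dipole field, and
#' scales to Hz at the metadata's field strength.
#'
#' @param chi 3D susceptibility volume in ppm.
#' @param meta [acquisition_meta()] providing B0, voxel size and direction.
#' @param pad_factor Zero-padding factor per axis (default 2).
#' @return Field volume in Hz on the input grid.
#' @export
forward_field <- function(chi, meta, pad_factor = 2) {
  shape <- dim(chi)
  if (any(shape < 8)) stop("grid must be at least 8 voxels per axis")
  pshape <- as.integer(shape * pad_factor)
  ker <- dipole_kernel(pshape, meta$voxel_size, meta$b0_direction)
  chip <- pad_array(chi, pshape)
  fp <- Re(ifftn(ker$values * fftn(chip)))
  field_ppm <- unpad_array(fp, shape)
  ppm_to_hz(field_ppm, meta$field_strength)
}

# evaluate the phi0 polynomial over normalized coordinates in [-1, 1]
phi0_field <- function(coef, shape, voxel_size) {
  g <- coord_grids(shape, voxel_size)
  ext <- shape * voxel_size
  xn <- 2 * g$x / ext[1] - 1
  yn <- 2 * g$y / ext[2] - 1
  zn <- 2 * g$z / ext[3] - 1
  terms <- list("1" = 1, x = xn, y = yn, z = zn, x2 = xn^2, y2 = yn^2,
                z2 = zn^2, xy = xn * yn, xz = xn * zn, yz = yn * zn)
  out <- array(0, shape)
  for (nm in names(coef)) {
    if (!nm %in% names(terms)) stop("unknown phi0 term: ", nm)
    out <- out + coef[[nm]] * terms[[nm]]
  }
  out
}

#' Simulate a multi-echo GRE acquisition of a phantom
#'
#' Signal model per voxel and echo:
#' `M0 * exp(-TE / T2*) * exp(i * (2*pi*f*TE + phi0))`, with `f` the forward
#' field of the in-brain plus background sources.  Complex Gaussian noise is
#' added in the complex domain at the requested first-echo SNR (so the phase
#' noise is magnitude-dependent and non-Gaussian, as in real data), the
#' result converted back to magnitude and phase, the phase multiplied by the
#' vendor sign and wrapped into `[-pi, pi)`.
#'
#' @param spec A [phantom_spec()].
#' @param meta [acquisition_meta()]; its voxel size should match the spec.
#' @param noiseless If `TRUE`, skip the noise step (ground-truth debugging).
#' @return List with `data` (a [multiecho_dataset()]) and `truth`, a list
#'   holding `chi` (ppm), `total_field`, `tissue_field`, `background_field`
#'   (Hz), `phi0` (rad), `brain_mask`, `label`, `t2star`, `magnitude`.
#' @export
simulate_multiecho <- function(spec, meta, noiseless = FALSE) {
  if (!(spec$snr > 0)) stop("snr must be > 0")
  scene <- build_chi_volume(spec, "all")
  tissue_chi <- build_chi_volume(spec, "tissue")$chi
  bg_chi <- build_chi_volume(spec, "background")$chi
  tissue_field <- forward_field(tissue_chi, meta)
  background_field <- forward_field(bg_chi, meta)
  total_field <- tissue_field + background_field
  phi0 <- phi0_field(spec$phi0_coef, spec$shape, spec$voxel_size)

  mags <- phases <- vector("list", length(meta$te))
  noise_sd <- mean(scene$magnitude[scene$brain_mask] *
                     exp(-meta$te[1] / scene$t2star[scene$brain_mask])) /
    spec$snr
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(spec$seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  for (e in seq_along(meta$te)) {
    te <- meta$te[e]
    amp <- scene$magnitude * exp(-te / scene$t2star)
    theta <- 2 * pi * total_field * te + phi0
    sig <- amp * exp(1i * theta)
    if (!noiseless) {
      n <- length(sig)
      sig <- sig + complex(real = rnorm(n, sd = noise_sd),
                           imaginary = rnorm(n, sd = noise_sd))
    }
    mags[[e]] <- array(Mod(sig), spec$shape)
    phases[[e]] <- wrap_phase(array(Arg(sig), spec$shape) * meta$phase_sign)
  }
  data <- multiecho_dataset(mags, phases, meta)
  truth <- list(chi = scene$chi, total_field = total_field,
                tissue_field = tissue_field,
                background_field = background_field, phi0 = phi0,
                brain_mask = scene$brain_mask, label = scene$label,
                t2star = scene$t2star, magnitude = scene$magnitude)
  list(data = data, truth = truth)
}

#' Default acquisition metadata matching the built-in phantom
#'
#' A 3 T protocol with five uniformly spaced echoes
#' (TE = 5.25 : 5.83 : 28.57 ms), TR = 33 ms, flip angle 15 degrees,
#' isotropic 2 mm voxels (matching the preset phantom grid) and B0 along
#' the third axis.
#'
#' @param phase_sign Vendor phase sign (default +1).
#' @param b0_direction Main-field direction (default `c(0, 0, 1)`).
#' @return An [acquisition_meta()].
#' @export
phantom_meta <- function(phase_sign = 1, b0_direction = c(0, 0, 1)) {
  acquisition_meta(
    field_strength = 3,
    te = (5.25 + 5.83 * 0:4) / 1000,
    tr = 0.033, flip_angle = 15,
    voxel_size = c(2, 2, 2), b0_direction = b0_direction,
    phase_sign = phase_sign,
    vendor = "synthetic", model = "qsmr numerical phantom",
    software = "qsmr")
}
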