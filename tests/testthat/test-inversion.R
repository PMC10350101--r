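test_that("dipole kernel takes its extreme values along and across B0 and obeys bounds", {
  ker <- dipole_kernel(c(16, 16, 16), c(1, 1, 1), c(0, 0, 1))
  # k parallel to B0: 1/3 - 1 = -2/3 ; k perpendicular: 1/3
  expect_equal(ker$values[1, 1, 2], -2 / 3)
  expect_equal(ker$values[2, 1, 1], 1 / 3)
  expect_equal(ker$values[1, 2, 1], 1 / 3)
  expect_equal(ker$values[1, 1, 1], 0)  # DC convention
  expect_true(all(ker$values >= -2 / 3 - 1e-12 & ker$values <= 1 / 3 + 1e-12))
  expect_error(dipole_kernel(c(8, 8, 8), c(1, 1, 1), c(0, 0, 0)), "nonzero")
})

test_that("kernel is symmetric under k -> -k and tracks oblique B0 directions", {
  # odd grid sizes so every frequency bin has a clean -k partner
  shape <- c(13, 11, 9)
  for (b0 in list(c(0, 0, 1), c(sin(0.3), 0, cos(0.3)),
                  c(0.2, -0.4, sqrt(1 - 0.04 - 0.16)))) {
    ker <- dipole_kernel(shape, c(1, 1.2, 2), b0)$values
    flipped <- ker[c(1, shape[1]:2), c(1, shape[2]:2), c(1, shape[3]:2)]
    expect_equal(ker, flipped, tolerance = 1e-12)
    # along the tilted B0 the kernel approaches -2/3, i.e. the magic-angle
    # cone rotates with the field direction
    expect_lt(min(ker), -0.6)
  }
})

test_that("the kernel's angular profile vanishes at the magic angle", {
  expect_equal(dipole_profile(0), -2 / 3)
  expect_equal(dipole_profile(90), 1 / 3)
  ang <- magic_angle()
  expect_equal(dipole_profile(ang), 0, tolerance = 1e-9)
  expect_equal(ang, acos(sqrt(1 / 3)) * 180 / pi, tolerance = 1e-6)
})

test_that("radians-to-ppm scaling reproduces the closed-form value and is linear", {
  expect_equal(scale_to_ppm(0, 3, 0.005), 0)
  expect_equal(scale_to_ppm(1, 3, 0.005), 0.2492, tolerance = 1e-4)
  expect_equal(scale_to_ppm(2, 3, 0.005), 2 * scale_to_ppm(1, 3, 0.005))
  expect_error(scale_to_ppm(1, -3, 0.005), "b0")
  expect_error(scale_to_ppm(1, 3, 0), "delta_te")
})

test_that("TKD inversion recovers a point source and smooths as the threshold grows", {
  meta <- acquisition_meta(3, 0.005, voxel_size = c(1, 1, 1))
  shape <- c(32, 32, 32)
  chi <- array(0, shape)
  chi[16, 16, 16] <- 1
  ker <- dipole_kernel(shape, c(1, 1, 1))
  f <- qsmr:::ppm_to_hz(Re(qsmr:::ifftn(ker$values * qsmr:::fftn(chi))), 3)
  inv <- tkd_invert(f, ker, meta = meta)
  expect_equal(which.max(inv$chi), which.max(chi))
  expect_rel_error(max(inv$chi), 1, 0.25)
  # zero field -> zero chi
  expect_equal(tkd_invert(array(0, shape), ker, meta = meta)$chi,
               array(0, shape))
  # near-maximal threshold smooths: total variation decreases
  tv_of <- function(m) {
    E <- qsmr:::grad_operators_k(shape)
    g <- lapply(E, function(e) Re(qsmr:::ifftn(e * qsmr:::fftn(m$chi))))
    qsmr:::tv_norm_iso(g[[1]], g[[2]], g[[3]])
  }
  hi <- tkd_invert(f, ker, threshold = 0.66, meta = meta)
  expect_lt(tv_of(hi), tv_of(inv))
})

test_that("TV inversion recovers a uniform sphere's susceptibility within 10%", {
  meta <- acquisition_meta(3, 0.005, voxel_size = c(1, 1, 1))
  shape <- c(48, 48, 48)
  g <- qsmr:::coord_grids(shape, c(1, 1, 1))
  r2 <- (g$x - 23.5)^2 + (g$y - 23.5)^2 + (g$z - 23.5)^2
  chi_true <- array(0.1 * (r2 <= 8^2), shape)
  ker <- dipole_kernel(shape, c(1, 1, 1))
  f <- qsmr:::ppm_to_hz(Re(qsmr:::ifftn(ker$values * qsmr:::fftn(chi_true))), 3)
  mask <- array(r2 <= 20^2, shape)
  sol <- tv_invert(f * mask, ker, meta = meta, valid_mask = mask)
  rel <- sol$chi - mean(sol$chi[mask])
  interior <- r2 <= 7^2
  expect_rel_error(mean(rel[interior]), 0.1, 0.10)
  # zero field -> zero chi
  z <- tv_invert(array(0, shape), ker, meta = meta, valid_mask = mask)
  expect_equal(z$chi, array(0, shape))
})

test_that("doubling lambda does not increase the solution's total variation", {
  meta <- acquisition_meta(3, 0.005, voxel_size = c(1, 1, 1))
  shape <- c(32, 32, 32)
  g <- qsmr:::coord_grids(shape, c(1, 1, 1))
  r2 <- (g$x - 15.5)^2 + (g$y - 15.5)^2 + (g$z - 15.5)^2
  chi_true <- array(0.1 * (r2 <= 6^2), shape)
  ker <- dipole_kernel(shape, c(1, 1, 1))
  set.seed(21)
  f <- qsmr:::ppm_to_hz(
    Re(qsmr:::ifftn(ker$values * qsmr:::fftn(chi_true))), 3) +
    array(rnorm(prod(shape), sd = 0.3), shape)
  mask <- array(r2 <= 13^2, shape)
  tv_of <- function(m) {
    E <- qsmr:::grad_operators_k(shape)
    gg <- lapply(E, function(e) Re(qsmr:::ifftn(e * qsmr:::fftn(m$chi))))
    qsmr:::tv_norm_iso(gg[[1]], gg[[2]], gg[[3]])
  }
  lo <- tv_invert(f * mask, ker, lambda_reg = 5e-4, meta = meta,
                  valid_mask = mask)
  hi <- tv_invert(f * mask, ker, lambda_reg = 1e-3, meta = meta,
                  valid_mask = mask)
  expect_lte(tv_of(hi), tv_of(lo))
  # determinism: repeated runs are bit-identical
  lo2 <- tv_invert(f * mask, ker, lambda_reg = 5e-4, meta = meta,
                   valid_mask = mask)
  expect_identical(lo$chi, lo2$chi)
})

test_that("TV solution fits the weighted data term at least as well as TKD", {
  meta <- acquisition_meta(3, 0.005, voxel_size = c(1, 1, 1))
  shape <- c(32, 32, 32)
  g <- qsmr:::coord_grids(shape, c(1, 1, 1))
  r2 <- (g$x - 15.5)^2 + (g$y - 15.5)^2 + (g$z - 15.5)^2
  chi_true <- array(0.1 * (r2 <= 6^2), shape)
  ker <- dipole_kernel(shape, c(1, 1, 1))
  f <- qsmr:::ppm_to_hz(Re(qsmr:::ifftn(ker$values * qsmr:::fftn(chi_true))), 3)
  mask <- array(r2 <= 13^2, shape)
  w <- array(as.numeric(mask), shape)
  resid <- function(chi) {
    b <- qsmr:::hz_to_ppm(f * mask, 3)
    sqrt(sum((w * (b - Re(qsmr:::ifftn(ker$values * qsmr:::fftn(chi)))))^2))
  }
  tv <- tv_invert(f * mask, ker, meta = meta, valid_mask = mask)
  tk <- tkd_invert(f * mask, ker, meta = meta, valid_mask = mask)
  expect_lte(resid(tv$chi), resid(tk$chi))
})

test_that("oblique acquisitions need the matching kernel direction", {
  b0_tilt <- c(sin(0.25), 0, cos(0.25))
  meta_t <- acquisition_meta(3, 0.005, voxel_size = c(1, 1, 1),
                             b0_direction = b0_tilt)
  meta_z <- acquisition_meta(3, 0.005, voxel_size = c(1, 1, 1))
  shape <- c(32, 32, 32)
  g <- qsmr:::coord_grids(shape, c(1, 1, 1))
  r2 <- (g$x - 15.5)^2 + (g$y - 15.5)^2 + (g$z - 15.5)^2
  chi_true <- array(0.1 * (r2 <= 6^2), shape)
  f <- forward_field(chi_true, meta_t)       # simulated with tilted B0
  mask <- array(r2 <= 13^2, shape)
  ker_t <- dipole_kernel(shape, c(1, 1, 1), b0_tilt)
  ker_z <- dipole_kernel(shape, c(1, 1, 1), c(0, 0, 1))
  good <- tkd_invert(f * mask, ker_t, meta = meta_t, valid_mask = mask)
  bad <- tkd_invert(f * mask, ker_z, meta = meta_z, valid_mask = mask)
  rmse <- function(m) {
    rel <- m$chi - mean(m$chi[mask])
    truth <- chi_true - mean(chi_true[mask])
    qsmr:::rms((rel - truth)[mask])
  }
  expect_lt(rmse(good), rmse(bad))
})

test_that("L-curve corner finding hits an injected corner and handles short grids", {
  lambdas <- 10^seq(-5, -2, length.out = 13)
  # synthetic L-curve: flat residual then steep rise after the corner at
  # index 7, monotone decreasing regularizer
  res <- c(rep(1, 7), exp(seq(0.5, 3, length.out = 6)))
  reg <- exp(seq(3, 0, length.out = 13))
  pick <- lcurve_corner(res, reg, lambdas)
  expect_equal(pick$index, 7, tolerance = 1)
  expect_warning(lcurve_corner(c(1, 2, 3), c(3, 2, 1), c(0.1, 0.2, 0.3)),
                 "middle lambda")
  expect_error(lcurve_select(array(0, c(8, 8, 8)), lambda_grid = c(1e-4)),
               "length")
})

test_that("L-curve selection over a lambda sweep lands near the RMSE-optimal lambda", {
  meta <- acquisition_meta(3, 0.005, voxel_size = c(1, 1, 1))
  shape <- c(32, 32, 32)
  g <- qsmr:::coord_grids(shape, c(1, 1, 1))
  r2 <- (g$x - 15.5)^2 + (g$y - 15.5)^2 + (g$z - 15.5)^2
  chi_true <- array(0.1 * (r2 <= 6^2), shape)
  ker <- dipole_kernel(shape, c(1, 1, 1))
  set.seed(5)
  f <- qsmr:::ppm_to_hz(
    Re(qsmr:::ifftn(ker$values * qsmr:::fftn(chi_true))), 3) +
    array(rnorm(prod(shape), sd = 0.15), shape)
  mask <- array(r2 <= 13^2, shape)
  grid <- 10^seq(-5, -2, length.out = 7)
  sel <- suppressWarnings(
    lcurve_select(f * mask, ker, lambda_grid = grid, meta = meta,
                  valid_mask = mask))
  rmse <- vapply(sel$maps, function(m) {
    rel <- m$chi - mean(m$chi[mask])
    truth <- chi_true - mean(chi_true[mask])
    qsmr:::rms((rel - truth)[mask])
  }, numeric(1))
  expect_lte(abs(sel$index - which.min(rmse)), 1)
})
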