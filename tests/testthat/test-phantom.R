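test_that("chi volume rasterization: identity, sphere fill, last-wins overlap", {
  ctr <- c(16, 16, 16)
  base <- function(prims) phantom_spec(
    shape = c(32, 32, 32), voxel_size = c(1, 1, 1), primitives = prims,
    brain_region = phantom_sphere(ctr, 14), snr = 50)

  empty <- build_chi_volume(base(list()), "tissue")
  expect_true(all(empty$chi == 0))

  one <- build_chi_volume(
    base(list(phantom_sphere(ctr, 10, chi = 0.1))), "tissue")
  g <- qsmr:::coord_grids(c(32, 32, 32), c(1, 1, 1))
  r2 <- (g$x - 16)^2 + (g$y - 16)^2 + (g$z - 16)^2
  expect_true(all(one$chi[r2 <= 81] == 0.1))   # clearly interior
  expect_true(all(one$chi[r2 > 121] == 0))     # clearly exterior

  two <- build_chi_volume(base(list(
    phantom_sphere(ctr + c(-3, 0, 0), 5, chi = 0.1),
    phantom_sphere(ctr + c(3, 0, 0), 5, chi = -0.1))), "tissue")
  expect_equal(two$chi[16, 16, 16], -0.1)      # overlap: later primitive wins
  expect_warning(
    build_chi_volume(base(list(phantom_sphere(c(200, 200, 200), 5, chi = 1))),
                     "tissue"),
    "outside the grid")
})

test_that("forward field of a uniform sphere matches the analytic dipole solution", {
  meta <- acquisition_meta(3, te = 0.005, voxel_size = c(1, 1, 1))
  shape <- c(64, 64, 64)
  ctr_mm <- c(31.5, 31.5, 31.5)  # voxel (32,32,32) center
  sp <- phantom_spec(shape = shape, voxel_size = c(1, 1, 1),
                     primitives = list(phantom_sphere(ctr_mm, 10, chi = 1)),
                     brain_region = phantom_sphere(ctr_mm, 20), snr = 50)
  chi <- build_chi_volume(sp, "tissue")$chi
  f_ppm <- qsmr:::hz_to_ppm(forward_field(chi, meta), 3)
  g <- qsmr:::coord_grids(shape, c(1, 1, 1))
  r2 <- (g$x - 31.5)^2 + (g$y - 31.5)^2 + (g$z - 31.5)^2
  # Lorentz-sphere result: zero mean shift inside a uniform sphere
  expect_lt(abs(mean(f_ppm[r2 <= 8^2])), 0.01)
  # external on-axis field at r = 2a: (dchi/3)(a/r)^3 * 2 = 0.0833 ppm
  expect_rel_error(f_ppm[32, 32, 52], (1 / 3) * (1 / 2)^3 * 2, 0.05)
  # zero susceptibility gives zero field
  expect_equal(forward_field(array(0, c(8, 8, 8)), meta),
               array(0, c(8, 8, 8)))
})

test_that("forward field is linear in susceptibility", {
  meta <- acquisition_meta(3, te = 0.005, voxel_size = c(2, 2, 2))
  set.seed(3)
  c1 <- array(rnorm(16^3, sd = 0.05), c(16, 16, 16))
  c2 <- array(rnorm(16^3, sd = 0.05), c(16, 16, 16))
  f12 <- forward_field(2 * c1 - 0.5 * c2, meta)
  expect_equal(f12, 2 * forward_field(c1, meta) - 0.5 * forward_field(c2, meta),
               tolerance = 1e-10)
})

test_that("ground truth decomposes into tissue plus background fields", {
  sim <- noiseless_sim()
  expect_equal(sim$truth$total_field,
               sim$truth$tissue_field + sim$truth$background_field,
               tolerance = 1e-12)
})

test_that("noiseless phase at TE1 reproduces the ground-truth field where unwrapped", {
  sim <- noiseless_sim()
  te1 <- phantom_meta()$te[1]
  tr <- sim$truth
  ok <- tr$brain_mask &
    abs(2 * pi * tr$total_field * te1 + tr$phi0) < pi - 0.1
  est <- (sim$data$phase[[1]][ok] - tr$phi0[ok]) / (2 * pi * te1)
  expect_equal(est, tr$total_field[ok], tolerance = 1e-9)
})

test_that("phase wrap boundary lands inside [-pi, pi)", {
  # f = 10 Hz at TE = 50 ms gives exactly pi of field phase
  meta <- acquisition_meta(3, te = 0.05, voxel_size = c(1, 1, 1))
  sp <- phantom_spec(shape = c(8, 8, 8), voxel_size = c(1, 1, 1),
                     brain_region = phantom_cuboid(c(4, 4, 4), c(8, 8, 8)),
                     snr = 50)
  ph <- qsmr:::wrap_phase(array(pi, c(8, 8, 8)))
  expect_true(all(ph >= -pi & ph < pi))
  expect_equal(ph[1, 1, 1], -pi)
  for (p in simulate_multiecho(sp, meta, noiseless = TRUE)$data$phase)
    expect_true(all(p >= -pi & p < pi))
})

test_that("identical spec and seed give a bit-identical dataset", {
  a <- simulate_multiecho(phantom_preset(seed = 5), phantom_meta())
  b <- simulate_multiecho(phantom_preset(seed = 5), phantom_meta())
  expect_identical(a$data$phase, b$data$phase)
  expect_identical(a$data$magnitude, b$data$magnitude)
  expect_error(
    phantom_spec(shape = c(8, 8, 8),
                 brain_region = phantom_sphere(c(4, 4, 4), 3), snr = 0),
    "snr")
})

test_that("complex-domain noise produces the expected first-echo phase noise", {
  # high-SNR propagation: sd(phase) ~ 1/SNR at the first echo
  sim <- noisy_sim(seed = 2)
  tr <- sim$truth
  # restrict to full-magnitude brain voxels away from strong gradients
  sel <- tr$label == 2 & tr$magnitude == 1
  te1 <- phantom_meta()$te[1]
  truth_phase <- qsmr:::wrap_phase(2 * pi * tr$total_field * te1 + tr$phi0)
  resid <- qsmr:::wrap_phase(sim$data$phase[[1]] - truth_phase)
  # at TE1 the brain-voxel amplitude is close to the brain-average
  # amplitude that sets the noise floor, so sd(phase) ~ 1/SNR
  expect_gt(sum(sel), 1e4)
  expect_rel_error(sd(resid[sel]), 1 / 50, 0.2)
})
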