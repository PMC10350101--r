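test_that("noiseless complex fit recovers field and offset to machine-level accuracy", {
  ds <- uniform_field_dataset(f_hz = 10, phi0 = 0.3)
  fit <- fit_complex_multiecho(ds)
  expect_lt(max(abs(fit$field - 10)), 1e-6)
  expect_lt(max(abs(fit$phi0 - 0.3)), 1e-6)
})

test_that("complex fit handles null signal and vendor sign", {
  ds0 <- uniform_field_dataset(f_hz = 0, phi0 = 0)
  fit0 <- fit_complex_multiecho(ds0)
  expect_equal(fit0$field, array(0, dim(fit0$field)))
  expect_equal(fit0$phi0, array(0, dim(fit0$phi0)))

  # all-zero magnitude voxels get quality 0 and zero field
  ds <- uniform_field_dataset(f_hz = 5, phi0 = 0.1)
  for (e in seq_along(ds$magnitude)) ds$magnitude[[e]][1, 1, 1] <- 0
  fit <- fit_complex_multiecho(ds)
  expect_equal(fit$quality[1, 1, 1], 0)
  expect_equal(fit$field[1, 1, 1], 0)

  # a negative vendor sign must not change the fitted (physical) field
  dsn <- uniform_field_dataset(f_hz = 7, phi0 = 0.2, phase_sign = -1)
  fitn <- fit_complex_multiecho(dsn)
  expect_lt(max(abs(fitn$field - 7)), 1e-6)

  expect_error(
    fit_complex_multiecho(uniform_field_dataset(te = c(5, 10) / 1000)),
    "3 echoes")
})

test_that("a field at the echo-spacing aliasing frequency fits to principal value zero", {
  te <- (5.25 + 5.83 * 0:4) / 1000
  ds <- uniform_field_dataset(f_hz = 1 / diff(te)[1], phi0 = 0, te = te)
  fit <- fit_complex_multiecho(ds)
  expect_lt(max(abs(fit$field)), 1e-6)
})

test_that("unwrapping is exact: output differs from input by integer multiples of 2*pi", {
  set.seed(11)
  shape <- c(24, 24, 24)
  g <- qsmr:::coord_grids(shape, c(1, 1, 1))
  truth <- 6 * pi * exp(-((g$x - 12)^2 + (g$y - 12)^2 + (g$z - 12)^2) /
                          (2 * 5^2))
  wrapped <- qsmr:::wrap_phase(truth)
  mask <- array(TRUE, shape)
  unw <- unwrap_spatial(wrapped, array(1, shape), mask)
  k <- (unw - wrapped) / (2 * pi)
  expect_equal(k, round(k), tolerance = 1e-9)
  # recovered up to one global 2*pi multiple
  off <- (unw - truth)[1, 1, 1]
  expect_equal(off / (2 * pi), round(off / (2 * pi)), tolerance = 1e-9)
  expect_lt(max(abs(unw - truth - off)), 1e-9)
})

test_that("unwrapping a constant volume changes nothing and empty masks error", {
  x <- array(0.5, c(8, 8, 8))
  expect_equal(unwrap_spatial(x, x, array(TRUE, c(8, 8, 8))), x,
               ignore_attr = TRUE)
  expect_error(unwrap_spatial(x, x, array(FALSE, c(8, 8, 8))), "empty")
})

test_that("disconnected mask components unwrap independently and are reported", {
  shape <- c(16, 8, 8)
  mask <- array(FALSE, shape)
  mask[2:6, 2:6, 2:6] <- TRUE
  mask[10:14, 2:6, 2:6] <- TRUE
  g <- qsmr:::coord_grids(shape, c(1, 1, 1))
  truth <- 0.8 * g$x
  wrapped <- qsmr:::wrap_phase(truth)
  expect_message(
    unw <- unwrap_spatial(wrapped, array(1, shape), mask),
    "2 disconnected")
  expect_equal(attr(unw, "n_components"), 2)
  for (xr in list(2:6, 10:14)) {
    sub <- unw[xr, 2:6, 2:6] - truth[xr, 2:6, 2:6]
    expect_lt(diff(range(sub)), 1e-9)  # internally consistent
  }
})

test_that("weighted echo averaging recovers the offset and matches the nonlinear fit", {
  ds <- uniform_field_dataset(f_hz = 4, phi0 = 0.7)
  te <- ds$meta$te
  # two-echo extrapolation of phi0 is exact on noiseless linear phase
  u1 <- array(2 * pi * 4 * te[1] + 0.7, dim(ds$phase[[1]]))
  u2 <- array(2 * pi * 4 * te[2] + 0.7, dim(ds$phase[[1]]))
  phi0 <- u1 - te[1] * (u2 - u1) / (te[2] - te[1])
  expect_equal(phi0[1, 1, 1], 0.7, tolerance = 1e-12)

  wa <- combine_weighted_average(ds)
  expect_lt(max(abs(wa$field - 4)), 1e-6)
  fit <- fit_complex_multiecho(ds)
  expect_lt(max(abs(wa$field - fit$field)), 1e-6)
  expect_error(
    combine_weighted_average(uniform_field_dataset(te = 0.005)),
    "2 echoes")
})

test_that("equal weights reproduce the ordinary least-squares slope", {
  ds <- uniform_field_dataset(f_hz = 6, phi0 = 0.4)
  te <- ds$meta$te
  wa <- combine_weighted_average(ds, weights = "equal")
  phases <- 2 * pi * 6 * te + 0.4
  ols <- coef(lm(phases ~ te))[2] / (2 * pi)
  expect_equal(wa$field[3, 3, 3], unname(ols), tolerance = 1e-9)
})

test_that("five-echo combination beats the single-echo estimate under noise", {
  # SNR benefit of multi-echo averaging, checked over 3 independent seeds
  te <- phantom_meta()$te
  for (seed in 1:3) {
    sim <- suppressMessages(
      simulate_multiecho(phantom_preset(seed = seed), phantom_meta()))
    tr <- sim$truth
    # full-signal brain voxels whose field is well below the echo-spacing
    # aliasing limit, so both estimators see the same wrap-free regime
    sel <- tr$label == 2 & tr$magnitude == 1 &
      abs(tr$total_field) < 0.25 / diff(te)[1]
    fit <- fit_complex_multiecho(sim$data)
    err_multi <- fit$field[sel] - tr$total_field[sel]
    # single-echo estimate from TE1 phase alone (offset known exactly)
    single <- qsmr:::wrap_phase(
      sim$data$phase[[1]] - qsmr:::wrap_phase(tr$phi0)) / (2 * pi * te[1])
    err_single <- single[sel] - tr$total_field[sel]
    # exclude wrap outliers from the single-echo error for a fair comparison
    ok <- abs(err_single) < 1 / (2 * te[1]) * 0.5
    expect_lt(sd(err_multi[ok]), sd(err_single[ok]))
  }
})

test_that("fit noise map is small where signal is strong and large where it is weak", {
  sim <- noisy_sim(seed = 1)
  fit <- fit_complex_multiecho(sim$data)
  tr <- sim$truth
  inside <- tr$label == 2
  outside <- tr$label == 0
  expect_lt(median(fit$noise[inside]), median(fit$noise[outside]) / 5)
  expect_true(all(fit$quality >= 0 & fit$quality <= 1))
  expect_true(all(fit$noise >= 0))
})
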