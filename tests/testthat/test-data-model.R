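test_that("acquisition metadata enforces its invariants", {
  expect_error(acquisition_meta(0, te = 0.005), "field_strength")
  expect_error(acquisition_meta(3, te = c(0.01, 0.005)), "increasing")
  expect_error(acquisition_meta(3, te = 0.005, b0_direction = c(0, 0, 2)),
               "unit norm")
  m <- acquisition_meta(3, te = c(5, 10, 15) / 1000)
  expect_s3_class(m, "qsm_meta")
  expect_equal(m$phase_sign, 1)
})

test_that("phase rescaling maps stored integer scales onto [-pi, pi)", {
  # 12-bit scale: midpoint to zero, three-quarter point to +pi/2
  expect_equal(rescale_phase(2048, 0, 4095), 0)
  expect_equal(rescale_phase(3072, 0, 4095), pi / 2)
  # extremes stay strictly inside the half-open interval
  expect_equal(rescale_phase(0, 0, 4095), -pi)
  expect_lt(rescale_phase(4095, 0, 4095), pi)
  expect_error(rescale_phase(1, 5, 5), "degenerate")
})

test_that("phase rescaling is idempotent on conformant input and applies the vendor sign", {
  x <- seq(-pi, pi - 1e-6, length.out = 100)
  expect_equal(rescale_phase(x, -pi, pi), x)
  # sign flip negates and re-wraps into the half-open interval
  flipped <- rescale_phase(x, -pi, pi, phase_sign = -1)
  expect_true(all(flipped >= -pi & flipped < pi))
  inner <- x > -pi  # -(-pi) = +pi wraps back to -pi; all others negate
  expect_equal(flipped[inner], -x[inner])
})

test_that("rescaled phase lies in [-pi, pi) for arbitrary stored ranges", {
  set.seed(42)
  for (i in 1:25) {
    lo <- runif(1, -100, 100)
    hi <- lo + runif(1, 0.5, 5000)
    vals <- runif(50, lo, hi)
    sgn <- sample(c(-1, 1), 1)
    out <- rescale_phase(vals, lo, hi, phase_sign = sgn)
    expect_true(all(out >= -pi & out < pi))
  }
})

test_that("NIfTI round trip preserves values, geometry and an off-center marker", {
  meta <- acquisition_meta(3, te = 0.005, voxel_size = c(1, 1.5, 2))
  vol <- array(rnorm(6 * 5 * 4), dim = c(6, 5, 4))
  vol[5, 2, 3] <- 99  # off-center marker
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, meta, path)
  img <- RNifti::readNifti(path)
  expect_identical(array(as.numeric(img), dim(img)), vol)
  # anisotropic voxel size survives in the header
  expect_equal(abs(RNifti::niftiHeader(img)$pixdim[2:4]), c(1, 1.5, 2))
  # the marker voxel's world coordinate is reproduced by the stored affine
  aff <- RNifti::xform(img)
  world <- aff %*% c(5 - 1, 2 - 1, 3 - 1, 1)
  expect_equal(drop(world)[1:3], c(4 * 1, 1 * 1.5, 2 * 2))
  expect_equal(which(img == 99, arr.ind = TRUE)[1, ], c(5, 2, 3),
               ignore_attr = TRUE)
})

test_that("loading multi-echo NIfTI + sidecar reconstructs the dataset and flags spacing", {
  dirp <- tempfile()
  dir.create(dirp)
  meta <- acquisition_meta(3, te = c(5.25, 11.08, 16.91, 22.74, 28.57) / 1000,
                           voxel_size = c(2, 2, 2))
  shape <- c(8, 8, 8)
  set.seed(1)
  magp <- phap <- character(5)
  for (e in 1:5) {
    magp[e] <- file.path(dirp, sprintf("mag%d.nii.gz", e))
    phap[e] <- file.path(dirp, sprintf("pha%d.nii.gz", e))
    write_volume(array(runif(prod(shape)), shape), meta, magp[e])
    write_volume(array(runif(prod(shape), -pi, pi - 0.01), shape), meta,
                 phap[e])
  }
  side <- file.path(dirp, "sidecar.json")
  jsonlite::write_json(list(EchoTimes_s = meta$te, FieldStrength_T = 3,
                            RepetitionTime_s = 0.033, FlipAngle_deg = 15,
                            PhaseSign = 1, B0Direction = c(0, 0, 1)),
                       side, auto_unbox = TRUE, digits = NA)
  ds <- load_multiecho(magp, phap, side)
  expect_length(ds$phase, 5)
  expect_true(ds$uniform_spacing)
  expect_equal(ds$meta$voxel_size, c(2, 2, 2))

  # single-echo pair is a valid dataset
  jsonlite::write_json(list(EchoTimes_s = 0.005, FieldStrength_T = 3),
                       side, auto_unbox = TRUE, digits = NA)
  ds1 <- load_multiecho(magp[1], phap[1], side)
  expect_length(ds1$phase, 1)

  # non-uniform spacing flagged, not an error
  jsonlite::write_json(list(EchoTimes_s = c(5, 10, 16) / 1000,
                            FieldStrength_T = 3),
                       side, auto_unbox = TRUE, digits = NA)
  ds2 <- load_multiecho(magp[1:3], phap[1:3], side)
  expect_false(ds2$uniform_spacing)
  expect_match(ds2$warnings, "non-uniform", all = FALSE)

  # echo-count mismatch and missing metadata are errors naming the problem
  expect_error(load_multiecho(magp[1:2], phap[1:3], side), "mismatch")
  jsonlite::write_json(list(EchoTimes_s = c(5, 10, 16) / 1000), side,
                       auto_unbox = TRUE, digits = NA)
  expect_error(load_multiecho(magp[1:3], phap[1:3], side), "FieldStrength_T")
})

test_that("pipeline configuration round-trips through serialization", {
  cfg <- pipeline_config(tv_lambda = 1e-3, bg_method = "pdf", seed = 9L)
  path <- tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2, cfg)
  expect_error(pipeline_config(nonsense = 1), "unknown config")
})
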