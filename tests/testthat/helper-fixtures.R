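# Shared fixtures, built once per test run.  The phantom simulations and the
# full pipeline run are the expensive pieces; individual tests reuse them.

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# noiseless preset simulation with full ground truth
noiseless_sim <- function() {
  get_fixture("noiseless_sim", function() {
    suppressMessages(
      simulate_multiecho(phantom_preset(seed = 7), phantom_meta(),
                         noiseless = TRUE))
  })
}

# noisy preset simulation (SNR 50)
noisy_sim <- function(seed = 1) {
  get_fixture(paste0("noisy_sim_", seed), function() {
    suppressMessages(
      simulate_multiecho(phantom_preset(seed = seed), phantom_meta()))
  })
}

# full default pipeline run on the phantom preset, with wall time recorded
pipeline_run <- function() {
  get_fixture("pipeline_run", function() {
    t0 <- Sys.time()
    res <- suppressMessages(suppressWarnings(
      run_pipeline(pipeline_config(seed = 1))))
    res$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  })
}

# V-SHARP / PDF applied to the noiseless ground-truth fields
background_runs <- function() {
  get_fixture("background_runs", function() {
    tr <- noiseless_sim()$truth
    vox <- phantom_meta()$voxel_size
    list(
      truth = tr,
      vs_total = suppressMessages(
        vsharp(tr$total_field, tr$brain_mask, voxel_size = vox)),
      vs_bg = suppressMessages(
        vsharp(tr$background_field, tr$brain_mask, voxel_size = vox)),
      pdf_total = suppressWarnings(
        pdf_background(tr$total_field, tr$brain_mask, voxel_size = vox)),
      pdf_bg = suppressWarnings(
        pdf_background(tr$background_field, tr$brain_mask,
                       voxel_size = vox)))
  })
}

# small synthetic multi-echo dataset with a spatially uniform field
uniform_field_dataset <- function(f_hz = 10, phi0 = 0.3,
                                  shape = c(12, 12, 12),
                                  te = (5.25 + 5.83 * 0:4) / 1000,
                                  phase_sign = 1) {
  meta <- acquisition_meta(3, te, voxel_size = c(2, 2, 2),
                           phase_sign = phase_sign)
  mags <- lapply(te, function(t) array(1, shape))
  phases <- lapply(te, function(t)
    qsmr:::wrap_phase(array(2 * pi * f_hz * t + phi0, shape) * phase_sign))
  multiecho_dataset(mags, phases, meta)
}

expect_rel_error <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
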