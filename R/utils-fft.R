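# n-dimensional FFT helpers and k-space grids.  stats::fft handles
# multidimensional arrays directly; these wrappers fix normalization and
# keep grid bookkeeping in one place.

fftn <- function(x) stats::fft(x)

ifftn <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' @noRd
fft_freq <- function(n, spacing = 1) {
  # unshifted DFT frequencies (cycles per unit), matching fft() bin order
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  k / (n * spacing)
}

# Cartesian k-grids as full arrays for a given shape/voxel size (mm).
kspace_grids <- function(shape, voxel_size) {
  kx <- fft_freq(shape[1], voxel_size[1])
  ky <- fft_freq(shape[2], voxel_size[2])
  kz <- fft_freq(shape[3], voxel_size[3])
  list(
    kx = array(kx, dim = shape),
    ky = array(rep(ky, each = shape[1]), dim = shape),
    kz = array(rep(kz, each = shape[1] * shape[2]), dim = shape)
  )
}

# Zero-pad an array symmetrically (original block at the start of each axis;
# position is irrelevant for circular convolution as long as kernel and data
# agree).  `unpad_array` recovers the original block.
pad_array <- function(x, shape, value = 0) {
  stopifnot(all(shape >= dim(x)))
  out <- array(value, dim = shape)
  d <- dim(x)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- x
  out
}

unpad_array <- function(x, shape) {
  x[seq_len(shape[1]), seq_len(shape[2]), seq_len(shape[3]), drop = FALSE]
}

# Circularly shift an array so that the element at `center` moves to
# [1,1,1]; used to express kernels built around the grid center in the
# wrap-around order that fft() expects.
ifftshift3 <- function(x, center) {
  d <- dim(x)
  idx <- lapply(seq_len(3), function(a) {
    ((seq_len(d[a]) - 1 + (center[a] - 1)) %% d[a]) + 1
  })
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

vox_mean <- function(x, mask) mean(x[mask])

rms <- function(x) sqrt(mean(x^2))
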