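# Small in-code fixtures shared across tests: a desk-scale phantom grid
# (20 x 20 x 16 at 3 mm) and a smooth Gaussian test volume for transform
# oracles.

small_dims <- c(20L, 20L, 16L)

# anisotropic radii so that every rotation axis is observable to the
# registrar (a sphere-like phantom leaves rotations ill-determined)
small_phantom <- function(asym = c(0, 0), base_c = 1e-4) {
  make_phantom(small_dims, c(3, 3, 3), brain_radii_mm = c(27, 21, 15),
               asym_coeffs = asym, base_c = base_c)
}

# Broad Gaussian blob: smooth everywhere, effectively zero at the border.
gaussian_volume <- function(dims = small_dims, voxel = c(3, 3, 3),
                            sigma_mm = 12) {
  ctr <- (dims - 1) / 2
  x <- (seq_len(dims[1]) - 1 - ctr[1]) * voxel[1]
  y <- (seq_len(dims[2]) - 1 - ctr[2]) * voxel[2]
  z <- (seq_len(dims[3]) - 1 - ctr[3]) * voxel[3]
  X <- array(x, dims)
  Y <- array(rep(y, each = dims[1]), dims)
  Z <- array(rep(z, each = dims[1] * dims[2]), dims)
  1000 * exp(-(X^2 + Y^2 + Z^2) / (2 * sigma_mm^2))
}

# A small rendered two-echo run with configurable truth; defaults give a
# quick zero-motion, zero-noise biased run.
small_run <- function(K = 40, asym = c(0, 0.5), base_c = 1e-4,
                      motion = NULL, noise_sd = 0, seed = 11L,
                      lowpass_hz = 0.1) {
  ph <- small_phantom(asym, base_c)
  cfg <- echo_config(c(13.7, 30), 3, K)
  truth <- list(
    motion = motion %||% motion_params(matrix(0, K, 6)),
    gs_driver = simulate_gs_driver(max(K, 12), 3, lowpass_hz, seed)[seq_len(K)],
    noise_sd = noise_sd, seed = seed + 1L)
  render_run(ph, cfg, truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
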