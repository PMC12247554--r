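# Synthetic multi-echo rsfMRI generator: ellipsoidal phantom with
# mono-exponential TE decay, a global BOLD fluctuation whose voxelwise
# coupling map can be made asymmetric along the posterior-anterior and
# inferior-superior axes, rigid-body head motion, and additive noise.
#
# Coordinate convention (shared with the registrar): grid axes (x, y, z),
# +x left, +y posterior, +z superior; translations in mm, rotations in
# degrees about the grid centre, composed as R = Rx %*% Ry %*% Rz.

#' Build an ellipsoidal multi-echo phantom
#'
#' Creates a smooth-edged ellipsoidal "brain" with baseline signal `s0`,
#' baseline relaxation rate R2* and a global-signal coupling map
#' `c(v) = base_c * max(0, 1 + a_y * yhat + a_z * zhat)` inside the brain,
#' where `yhat, zhat` are coordinates normalized to `[-1, 1]` over the
#' ellipsoid (`yhat = +1` posterior, `zhat = +1` superior). `c(v)` is the
#' change in R2* (1/ms) per unit of the dimensionless global driver, so at
#' echo time TE the fractional BOLD signal change is approximately
#' `TE * c(v)` per driver unit.
#'
#' @param grid_dims Integer 3-vector of grid dimensions (each >= 16).
#' @param voxel_size_mm Numeric 3-vector, voxel size in mm.
#' @param brain_radii_mm Numeric 3-vector, ellipsoid semi-axes in mm; must
#'   fit inside the grid.
#' @param asym_coeffs Numeric 2-vector `(a_y, a_z)`: dimensionless gradients
#'   of the coupling map along posterior->anterior and inferior->superior.
#' @param base_c Baseline coupling (1/ms per driver unit). Default `1e-4`
#'   gives an echo-2 (30 ms) global percent-change amplitude of about 0.3%
#'   for a unit-variance driver.
#' @param s0 Baseline signal intensity inside the brain (arbitrary units).
#' @param r2s Baseline R2* (1/ms); default 0.022 (T2* ~ 45 ms).
#' @param edge_mm Width of the smooth (cosine-tapered) ellipsoid edge in mm.
#' @param texture_amp Amplitude of the smooth internal intensity modulation
#'   (fraction of `s0`). Real EPI volumes have gray/white/CSF contrast that
#'   makes rotations well-determined; a uniform ellipsoid is unrealistically
#'   information-poor for in-plane rotation. The modulation is a fixed
#'   product of cosines (even in every axis, so the phantom's mirror
#'   symmetries are preserved).
#' @return An object of class `phantom` with fields `s0_map`, `r2s_map`,
#'   `coupling_map`, `brain_mask`, `voxel_size_mm`, `asym_coeffs`.
#' @export
make_phantom <- function(grid_dims = c(32L, 32L, 24L),
                         voxel_size_mm = c(3, 3, 3),
                         brain_radii_mm = c(36, 42, 30),
                         asym_coeffs = c(0, 0),
                         base_c = 1e-4,
                         s0 = 1000,
                         r2s = 0.022,
                         edge_mm = 4,
                         texture_amp = 0.2) {
  stopifnot(length(grid_dims) == 3, length(voxel_size_mm) == 3,
            length(brain_radii_mm) == 3, length(asym_coeffs) == 2)
  if (any(grid_dims < 16))
    stop("grid_dims must be at least 16 per axis")
  half_extent <- (grid_dims - 1) / 2 * voxel_size_mm
  if (any(brain_radii_mm > half_extent))
    stop("brain ellipsoid exceeds the grid: radii ",
         paste(brain_radii_mm, collapse = "x"), " mm vs half-extent ",
         paste(round(half_extent, 1), collapse = "x"), " mm")

  ctr <- (grid_dims - 1) / 2
  x <- (seq_len(grid_dims[1]) - 1 - ctr[1]) * voxel_size_mm[1]
  y <- (seq_len(grid_dims[2]) - 1 - ctr[2]) * voxel_size_mm[2]
  z <- (seq_len(grid_dims[3]) - 1 - ctr[3]) * voxel_size_mm[3]
  X <- array(x, grid_dims)
  Y <- array(rep(y, each = grid_dims[1]), grid_dims)
  Z <- array(rep(z, each = grid_dims[1] * grid_dims[2]), grid_dims)

  rho <- sqrt((X / brain_radii_mm[1])^2 + (Y / brain_radii_mm[2])^2 +
                (Z / brain_radii_mm[3])^2)
  # cosine taper from 1 (inside) to 0 across an edge shell of width edge_mm
  edge_frac <- edge_mm / mean(brain_radii_mm)
  w <- 0.5 * (1 + cos(pmin(pmax((rho - (1 - edge_frac)) / edge_frac, 0), 1) * pi))
  mask <- rho <= 1

  yhat <- Y / brain_radii_mm[2]
  zhat <- Z / brain_radii_mm[3]
  cmap <- base_c * pmax(0, 1 + asym_coeffs[1] * yhat + asym_coeffs[2] * zhat)
  cmap <- cmap * w
  cmap[!mask] <- 0

  texture <- 1 + texture_amp * cos(2 * pi * X / 23) *
    cos(2 * pi * Y / 31) * cos(2 * pi * Z / 17)
  s0_map <- s0 * w * texture
  s0_map[rho > 1] <- 0

  structure(list(s0_map = s0_map,
                 r2s_map = array(r2s, grid_dims) * (s0_map > 0),
                 coupling_map = cmap,
                 brain_mask = mask,
                 voxel_size_mm = voxel_size_mm,
                 asym_coeffs = asym_coeffs,
                 brain_radii_mm = brain_radii_mm),
            class = "phantom")
}

#' Simulate a smooth global-signal driver
#'
#' White Gaussian noise low-pass filtered in the frequency domain (all
#' components above `lowpass_hz` removed), then exactly standardized to
#' mean 0 and sample SD 1. Emulates the slow resting-state global BOLD
#' fluctuation.
#'
#' @param K Number of time points (>= 10).
#' @param tr_s Repetition time in seconds.
#' @param lowpass_hz Low-pass cutoff in Hz; must be below Nyquist.
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return Numeric length-K vector, mean 0, SD 1.
#' @export
simulate_gs_driver <- function(K, tr_s = 3, lowpass_hz = 0.1, seed = 1L) {
  stopifnot(K >= 10)
  nyq <- 1 / (2 * tr_s)
  if (lowpass_hz >= nyq)
    stop("lowpass_hz (", lowpass_hz, ") must be below Nyquist (", nyq, " Hz)")
  x <- with_seed(seed, rnorm(K))
  f <- c(0, seq_len(K - 1)) / (K * tr_s)
  f <- pmin(f, 1 / tr_s - f)  # two-sided frequency axis
  xf <- stats::fft(x)
  xf[f > lowpass_hz] <- 0
  x <- Re(stats::fft(xf, inverse = TRUE)) / K
  x <- x - mean(x)
  s <- sd(x)
  if (s == 0) stop("degenerate driver (all frequency components removed)")
  x / s
}

#' Simulate ground-truth rigid-body head motion
#'
#' Profiles: `"none"` (all zeros), `"drift"` (smooth low-frequency
#' wandering), `"spikes"` (`n_spikes` isolated frames displaced by up to
#' `amplitude_mm_deg`), `"mixed"` (drift plus spikes). The first row is
#' always zero: the reference frame does not move.
#'
#' @param K Number of frames.
#' @param profile One of `"none"`, `"drift"`, `"spikes"`, `"mixed"`.
#' @param amplitude_mm_deg Peak amplitude in mm (translations) and degrees
#'   (rotations).
#' @param seed Integer seed.
#' @param n_spikes Number of spike frames for the spike profiles.
#' @return A `motion_params` object (K x 6 matrix, columns Rx Ry Rz Tx Ty Tz,
#'   movement-of-volume sign convention, reference index 1).
#' @export
simulate_motion <- function(K, profile = c("none", "drift", "spikes", "mixed"),
                            amplitude_mm_deg = 0.1, seed = 1L, n_spikes = 3L) {
  profile <- match.arg(profile)
  stopifnot(amplitude_mm_deg >= 0, K >= 2)
  m <- matrix(0, K, 6)
  if (profile != "none" && amplitude_mm_deg > 0) {
    m <- with_seed(seed, {
      out <- matrix(0, K, 6)
      if (profile %in% c("drift", "mixed")) {
        flen <- max(3, min(15, K - 1))
        for (a in 1:6) {
          w <- cumsum(rnorm(K))
          w <- stats::filter(w, rep(1 / flen, flen), sides = 2,
                             circular = TRUE)
          w <- as.numeric(w) - as.numeric(w)[1]
          pk <- max(abs(w))
          if (pk > 0) out[, a] <- w / pk * amplitude_mm_deg * runif(1, 0.5, 1)
        }
      }
      if (profile %in% c("spikes", "mixed")) {
        frames <- sample(3:K, n_spikes)
        for (t in frames) {
          row <- runif(6, -1, 1)
          row <- row / max(abs(row)) * amplitude_mm_deg * runif(1, 0.5, 1)
          out[t, ] <- out[t, ] + row
        }
      }
      out
    })
    m[1, ] <- 0
  }
  motion_params(m, reference_index = 1L)
}

#' Construct a motion-parameter object
#'
#' @param values K x 6 numeric matrix, columns (Rx, Ry, Rz) in degrees and
#'   (Tx, Ty, Tz) in mm.
#' @param sign_convention Only `"movement_of_volume"` is supported: each row
#'   is the displacement of that frame relative to the reference.
#' @param reference_index 1-based index of the reference frame (row must be
#'   all zero).
#' @return A `motion_params` object.
#' @export
motion_params <- function(values, sign_convention = "movement_of_volume",
                          reference_index = 1L) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == 6, all(is.finite(values)))
  if (any(values[reference_index, ] != 0))
    stop("reference frame row must be all zero")
  colnames(values) <- axis_names()
  structure(values, class = c("motion_params", "matrix"),
            sign_convention = sign_convention,
            reference_index = as.integer(reference_index))
}

#' Render a synthetic multi-echo run
#'
#' Signal law per voxel, frame and echo:
#' `S_i(v, t) = s0(v) * exp(-TE_i * (r2s(v) - c(v) * gs(t)))`, followed by a
#' rigid transform of the whole volume by that frame's ground-truth motion
#' (movement-of-volume convention), followed by additive Gaussian noise.
#' The full exponential is simulated, so the linearized percent-change
#' approximation `100 * TE_i * c(v) * gs(t)` is a testable property, not an
#' assumption. Negative instantaneous R2* is clamped to 0 with a warning;
#' final intensities are clamped at 0.
#'
#' @param phantom A [make_phantom()] object.
#' @param echo_cfg List with `te_ms` (strictly increasing, > 0), `tr_s`,
#'   `n_volumes`.
#' @param truth List with `motion` (`motion_params`, K rows), `gs_driver`
#'   (length K), `noise_sd` (>= 0), `seed`.
#' @param interp_order Interpolation order for the motion warp (3 = cubic).
#' @return A `multi_echo_run`: list with `echoes` (list of 4-D arrays),
#'   `te_ms`, `tr_s`, `voxel_size_mm`, `truth`, `phantom`.
#' @export
render_run <- function(phantom, echo_cfg, truth, interp_order = 3L) {
  te <- echo_cfg$te_ms
  stopifnot(length(te) >= 2, all(diff(te) > 0), all(te > 0))
  K <- echo_cfg$n_volumes
  stopifnot(nrow(truth$motion) == K, length(truth$gs_driver) == K)
  dims <- dim(phantom$s0_map)
  n_clamped <- 0L
  echoes <- lapply(te, function(.) array(0, c(dims, K)))
  noise_sd <- truth$noise_sd %||% 0

  vols <- with_seed(truth$seed %||% 1L, {
    for (t in seq_len(K)) {
      r2 <- phantom$r2s_map - phantom$coupling_map * truth$gs_driver[t]
      neg <- r2 < 0
      if (any(neg)) {
        n_clamped <- n_clamped + sum(neg)
        r2[neg] <- 0
      }
      mv <- truth$motion[t, ]
      for (e in seq_along(te)) {
        vol <- phantom$s0_map * exp(-te[e] * r2)
        if (any(mv != 0))
          vol <- array(cpp_rigid_warp(vol, dims, phantom$voxel_size_mm,
                                      as.numeric(mv), FALSE, interp_order),
                       dims)
        if (noise_sd > 0)
          vol <- vol + array(rnorm(prod(dims), sd = noise_sd), dims)
        echoes[[e]][, , , t] <- pmax(vol, 0)
      }
    }
    echoes
  })
  if (n_clamped > 0)
    warning("negative instantaneous R2* clamped to 0 at ", n_clamped,
            " voxel-frames")
  structure(list(echoes = vols, te_ms = te, tr_s = echo_cfg$tr_s,
                 voxel_size_mm = phantom$voxel_size_mm,
                 truth = truth, phantom = phantom),
            class = "multi_echo_run")
}

#' Default echo configuration
#'
#' Two-echo EPI-like protocol at desk scale: TEs 13.7 and 30 ms, TR 3 s.
#'
#' @param te_ms Echo times in ms.
#' @param tr_s Repetition time in s.
#' @param n_volumes Number of frames K.
#' @return List with the three fields.
#' @export
echo_config <- function(te_ms = c(13.7, 30), tr_s = 3, n_volumes = 200L) {
  stopifnot(length(te_ms) >= 2, all(diff(te_ms) > 0), all(te_ms > 0),
            n_volumes >= 2)
  list(te_ms = te_ms, tr_s = tr_s, n_volumes = as.integer(n_volumes))
}
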