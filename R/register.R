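# Rigid-body intensity least-squares registration with uniform weights:
# the estimator whose global-signal bias the rest of the package
# characterizes. Gauss-Newton on the 6 rigid parameters, with the Jacobian
# built from central-difference spatial derivative images of the reference
# volume (the same images the spatial decomposition uses).

#' Derivative-step configuration
#'
#' Central-difference step sizes for the spatial derivative images: 2.1 mm
#' for translations and 0.4 degrees for rotations (the steps a standard
#' rigid registrar derives from 3 mm voxels), plus the interpolation order.
#'
#' @param eps_trans_mm Translation step (mm), > 0.
#' @param eps_rot_deg Rotation step (degrees), > 0.
#' @param interp_order Interpolation order (3 = cubic).
#' @return A `deriv_config` list.
#' @export
deriv_config <- function(eps_trans_mm = 2.1, eps_rot_deg = 0.4,
                         interp_order = 3L) {
  stopifnot(eps_trans_mm > 0, eps_rot_deg > 0)
  structure(list(eps_trans_mm = eps_trans_mm, eps_rot_deg = eps_rot_deg,
                 interp_order = as.integer(interp_order)),
            class = "deriv_config")
}

#' Rigid-body transform of a volume
#'
#' Moves the volume by `params = (Rx, Ry, Rz, Tx, Ty, Tz)` (degrees, mm)
#' about the grid centre, rotation composed as `Rx %*% Ry %*% Rz`, in the
#' movement-of-volume convention. All-zero parameters return the input
#' bit-exactly. Out-of-field voxels are 0.
#'
#' @param vol 3-D numeric array.
#' @param params Numeric 6-vector, finite.
#' @param voxel_size_mm Numeric 3-vector.
#' @param interp_order 0 (nearest), 1 (trilinear) or 3 (cubic).
#' @param invert Apply the inverse rigid transform instead (used to resample
#'   a moved frame back onto the reference grid).
#' @return 3-D numeric array, same dimensions.
#' @export
transform_volume <- function(vol, params, voxel_size_mm = c(3, 3, 3),
                             interp_order = 3L, invert = FALSE) {
  if (!all(is.finite(params)) || length(params) != 6)
    stop("params must be 6 finite values")
  if (all(params == 0)) return(vol)
  dims <- dim(vol)
  array(cpp_rigid_warp(vol, dims, voxel_size_mm, as.numeric(params),
                       invert, as.integer(interp_order)), dims)
}

#' Spatial derivative image of a reference volume
#'
#' Central difference of the reference volume transformed by +eps and -eps
#' along one motion axis: `d = (T(ref, +eps) - T(ref, -eps)) / (2 eps)`.
#' Units are intensity per mm (translations) or per degree (rotations).
#'
#' @param ref 3-D reference volume.
#' @param axis One of `"Rx","Ry","Rz","Tx","Ty","Tz"`.
#' @param cfg A [deriv_config()].
#' @param voxel_size_mm Voxel size (mm).
#' @return List with `values` (3-D array), `axis`, `eps`.
#' @export
spatial_derivative <- function(ref, axis, cfg = deriv_config(),
                               voxel_size_mm = c(3, 3, 3)) {
  ax <- match(axis, axis_names())
  if (is.na(ax)) stop("unknown motion axis: ", axis)
  eps <- if (ax <= 3) cfg$eps_rot_deg else cfg$eps_trans_mm
  p <- rep(0, 6)
  p[ax] <- eps
  plus <- transform_volume(ref, p, voxel_size_mm, cfg$interp_order)
  p[ax] <- -eps
  minus <- transform_volume(ref, p, voxel_size_mm, cfg$interp_order)
  list(values = (plus - minus) / (2 * eps), axis = axis, eps = eps)
}

# N x 6 Jacobian of T(ref; m) at m = 0: one derivative image per axis.
reference_jacobian <- function(ref, cfg, voxel_size_mm) {
  J <- vapply(axis_names(),
              function(a) as.numeric(spatial_derivative(ref, a, cfg,
                                                        voxel_size_mm)$values),
              numeric(length(ref)))
  colnames(J) <- axis_names()
  J
}

#' Register one volume to a reference
#'
#' Estimates the 6 rigid-body movement-of-volume parameters `m` by
#' Gauss-Newton least squares on `sum_v (T(ref; m)(v) - vol(v))^2` with
#' uniform voxel weights (every voxel counts equally). Solving for the
#' movement of the volume directly is equivalent, to first order, to
#' finding the aligning transform of `vol` and negating it, and avoids the
#' second-order error of negating rigid parameters. The Jacobian is the
#' reference volume's six derivative images, computed once (set
#' `refresh_jacobian = TRUE` to recompute it at the current estimate each
#' iteration). Iteration stops when the largest parameter update falls
#' below `tol` or after `max_iter` iterations. Steps that increase the SSE
#' are rejected, so the SSE is non-increasing across accepted iterations;
#' after a rejected step the Jacobian is recomputed once at the current
#' estimate (where the frozen reference Jacobian is no longer a good local
#' model) before giving up.
#'
#' @param vol 3-D volume to register.
#' @param ref 3-D reference volume (nonzero variance).
#' @param init Initial 6-vector (movement-of-volume).
#' @param cfg A [deriv_config()].
#' @param tol Convergence tolerance on the parameter update (mm / deg).
#' @param max_iter Maximum Gauss-Newton iterations.
#' @param voxel_size_mm Voxel size (mm).
#' @param jacobian Optional precomputed reference Jacobian (from
#'   `reference_jacobian`); used by [register_run()] to share it across
#'   frames.
#' @param compute_registered Also resample the input volume back onto the
#'   reference grid (skip to save a warp when only parameters are needed).
#' @param refresh_jacobian Recompute the Jacobian at the current estimate
#'   each iteration.
#' @param refine_threshold When the frozen-Jacobian estimate exceeds this
#'   magnitude (mm / deg) on any axis, re-linearize once at the estimate and
#'   refine: the frozen fixed point carries a quadratic parameter bias that
#'   becomes relevant for rotations beyond a few tenths of a degree, while
#'   small-motion frames skip the extra cost.
#' @return List with `params` (6-vector, movement-of-volume), `registered`
#'   (the input volume resampled back onto the reference grid), `sse`,
#'   `converged`, `iterations`.
#' @export
register_volume <- function(vol, ref, init = rep(0, 6), cfg = deriv_config(),
                            tol = 0.001, max_iter = 20L,
                            voxel_size_mm = c(3, 3, 3),
                            jacobian = NULL, refresh_jacobian = FALSE,
                            refine_threshold = 0.15,
                            compute_registered = TRUE) {
  stopifnot(all(dim(vol) == dim(ref)))
  if (sd(ref) == 0) stop("reference volume has zero variance")
  if (is.null(jacobian))
    jacobian <- reference_jacobian(ref, cfg, voxel_size_mm)
  JtJ <- crossprod(jacobian)
  check_normal_equations(JtJ)

  m <- as.numeric(init)
  v <- as.numeric(vol)
  cur <- as.numeric(transform_volume(ref, m, voxel_size_mm, cfg$interp_order))
  sse <- sum((cur - v)^2)
  converged <- FALSE
  it <- 0L
  J <- jacobian
  refreshed_at <- NULL
  while (it < max_iter) {
    it <- it + 1L
    if (refresh_jacobian && any(m != 0)) {
      J <- jacobian_at(ref, m, cfg, voxel_size_mm)
      JtJ <- crossprod(J)
      check_normal_equations(JtJ)
    }
    delta <- as.numeric(solve(JtJ, crossprod(J, v - cur)))
    m_new <- m + delta
    cur_new <- as.numeric(transform_volume(ref, m_new, voxel_size_mm,
                                           cfg$interp_order))
    sse_new <- sum((cur_new - v)^2)
    if (sse_new > sse) {
      # reject the step (SSE must not increase); a sub-tolerance rejected
      # step means we are at the noise floor of the cost surface
      if (max(abs(delta)) < tol) {
        converged <- TRUE
        break
      }
      # otherwise re-linearize at the current estimate once before giving up
      if (!identical(refreshed_at, m)) {
        J <- jacobian_at(ref, m, cfg, voxel_size_mm)
        JtJ <- crossprod(J)
        check_normal_equations(JtJ)
        refreshed_at <- m
        next
      }
      break
    }
    m <- m_new
    cur <- cur_new
    sse <- sse_new
    if (max(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  # secant refinement: one re-linearization at the estimate removes the
  # quadratic bias of the frozen-Jacobian fixed point at larger motions
  if (!refresh_jacobian && max(abs(m)) > refine_threshold) {
    for (round in 1:2) {
      J <- jacobian_at(ref, m, cfg, voxel_size_mm)
      JtJ <- crossprod(J)
      check_normal_equations(JtJ)
      moved <- FALSE
      for (sub in 1:5) {
        it <- it + 1L
        delta <- as.numeric(solve(JtJ, crossprod(J, v - cur)))
        m_new <- m + delta
        cur_new <- as.numeric(transform_volume(ref, m_new, voxel_size_mm,
                                               cfg$interp_order))
        sse_new <- sum((cur_new - v)^2)
        if (sse_new > sse) break
        if (max(abs(m_new - m)) >= tol) moved <- TRUE
        m <- m_new
        cur <- cur_new
        sse <- sse_new
        if (max(abs(delta)) < tol) {
          converged <- TRUE
          break
        }
      }
      if (!moved) break
    }
  }
  if (!converged && it >= max_iter)
    warning("registration did not converge in ", max_iter, " iterations")
  registered <- if (compute_registered)
    transform_volume(vol, m, voxel_size_mm, cfg$interp_order, invert = TRUE)
  list(params = stats::setNames(m, axis_names()), registered = registered,
       sse = sse, converged = converged, iterations = it)
}

# Central-difference Jacobian of T(ref; m) at the current estimate m.
jacobian_at <- function(ref, m, cfg, voxel_size_mm) {
  J <- matrix(0, length(ref), 6, dimnames = list(NULL, axis_names()))
  for (ax in 1:6) {
    eps <- if (ax <= 3) cfg$eps_rot_deg else cfg$eps_trans_mm
    p <- m
    p[ax] <- p[ax] + eps
    plus <- transform_volume(ref, p, voxel_size_mm, cfg$interp_order)
    p[ax] <- p[ax] - 2 * eps
    minus <- transform_volume(ref, p, voxel_size_mm, cfg$interp_order)
    J[, ax] <- (plus - minus) / (2 * eps)
  }
  J
}

check_normal_equations <- function(JtJ) {
  d <- svd(JtJ, nu = 0, nv = 6)
  if (d$d[6] <= d$d[1] * 1e-12) {
    worst <- axis_names()[which.max(abs(d$v[, 6]))]
    stop("singular normal equations; degenerate axis: ", worst)
  }
}

#' Register every frame of a 4-D run
#'
#' Registers each frame to the frame at `reference_index` with
#' [register_volume()], initializing each frame from the previous frame's
#' estimate. The reference Jacobian is computed once and shared.
#'
#' @param run4d 4-D numeric array (x, y, z, time), K >= 2.
#' @param reference_index 1-based reference frame index.
#' @param cfg A [deriv_config()].
#' @param voxel_size_mm Voxel size (mm).
#' @param tol,max_iter Passed to [register_volume()].
#' @param return_registered Also return the registered 4-D array.
#' @return A `motion_params` object (movement-of-volume convention); if
#'   `return_registered`, a list with `params` and `registered`.
#' @export
register_run <- function(run4d, reference_index = 1L, cfg = deriv_config(),
                         voxel_size_mm = c(3, 3, 3), tol = 0.001,
                         max_iter = 20L, return_registered = FALSE) {
  K <- dim(run4d)[4]
  stopifnot(K >= 2)
  ref <- run4d[, , , reference_index]
  J <- reference_jacobian(ref, cfg, voxel_size_mm)
  params <- matrix(0, K, 6)
  reg <- if (return_registered) run4d else NULL
  prev <- rep(0, 6)
  for (t in seq_len(K)) {
    if (t == reference_index) {
      prev <- rep(0, 6)
      next
    }
    fit <- tryCatch(
      register_volume(run4d[, , , t], ref, init = prev, cfg = cfg, tol = tol,
                      max_iter = max_iter, voxel_size_mm = voxel_size_mm,
                      jacobian = J, compute_registered = return_registered),
      error = function(e) stop("frame ", t, ": ", conditionMessage(e)))
    params[t, ] <- fit$params
    if (return_registered) reg[, , , t] <- fit$registered
    prev <- fit$params
  }
  mp <- motion_params(params, reference_index = as.integer(reference_index))
  if (return_registered) list(params = mp, registered = reg) else mp
}
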