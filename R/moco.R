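#' Motion vector field container
#'
#' Dense displacement field (mm) on a volume grid mapping coordinates of one
#' phase to the next. Carries the regularization scales it was estimated
#' with and convergence metadata.
#'
#' @param u 4D array (nx, ny, nz, 3) of displacements in mm.
#' @param voxel grid spacing mm; @param origin grid origin mm.
#' @param params named list of estimation parameters / metadata.
#' @export
motion_vector_field <- function(u, voxel, origin, params = list()) {
  stopifnot(length(dim(u)) == 4, dim(u)[4] == 3)
  if (any(!is.finite(u))) stop("displacement field contains non-finite values")
  structure(list(u = u, voxel = voxel, origin = origin, params = params),
            class = "motion_vector_field")
}

field_dims <- function(f) dim(f$u)[1:3]

#' Warp a volume by a displacement field
#'
#' \code{out(x) = vol(x + u(x))} with trilinear interpolation (border
#' clamped); intensity-only resampling without Jacobian density weighting.
#'
#' @param vol a \code{ct_volume}; @param field a \code{motion_vector_field}
#'   on the same grid.
#' @export
warp_volume <- function(vol, field) {
  stopifnot(all(dim(vol$data) == field_dims(field)))
  out <- cpp_warp(as.numeric(vol$data), as.numeric(field$u), dim(vol$data),
                  vol$voxel)
  v <- vol
  v$data <- array(out, dim = dim(vol$data))
  v$provenance$warped <- TRUE
  v
}

#' Compose two displacement fields
#'
#' \code{(a then b)(x) = a(x) + b(x + a(x))}: the returned field maps
#' through both transforms.
#' @param a,b \code{motion_vector_field}s on the same grid.
#' @export
compose_fields <- function(a, b) {
  d <- field_dims(a)
  out <- cpp_compose_fields(as.numeric(a$u), as.numeric(b$u), d, a$voxel)
  motion_vector_field(array(out, dim = c(d, 3)), a$voxel, a$origin,
                      list(composed = TRUE))
}

#' Approximate inverse of a displacement field
#' @param f a \code{motion_vector_field}; @param iters fixed-point iterations.
#' @export
invert_field <- function(f, iters = 15) {
  d <- field_dims(f)
  out <- cpp_invert_field(as.numeric(f$u), d, f$voxel, iters)
  motion_vector_field(array(out, dim = c(d, 3)), f$voxel, f$origin,
                      list(inverse = TRUE))
}

zero_field <- function(dims, voxel, origin) {
  motion_vector_field(array(0, dim = c(dims, 3)), voxel, origin)
}

max_displacement_vox <- function(f) {
  d <- field_dims(f)
  nv <- prod(d)
  u <- matrix(f$u, nv, 3)
  max(sqrt(rowSums(u^2))) / f$voxel
}

#' Demons deformable registration
#'
#' Multi-resolution (default 3 levels) Thirion demons with symmetric forces
#' and Gaussian fluid/diffusion regularization, minimizing an SSD surrogate.
#' Images are lightly pre-smoothed before force computation (registration
#' accuracy degrades with noise); the returned field applies to the raw
#' volumes.
#'
#' @param fixed,moving \code{ct_volume}s on the same grid, comparable units.
#' @param levels pyramid levels; @param iterations per level, coarsest first.
#' @param sigma_fluid,sigma_diff regularization scales (voxels).
#' @param presmooth Gaussian pre-smoothing (voxels) for force computation.
#' @param max_step maximum update step per iteration (voxels).
#' @return a \code{motion_vector_field} mapping fixed-grid coordinates into
#'   the moving volume, with residual history in \code{params}.
#' @export
demons_register <- function(fixed, moving, levels = 3,
                            iterations = c(50, 30, 20), sigma_fluid = 1.5,
                            sigma_diff = 1.5, presmooth = 1.0,
                            max_step = 1.0) {
  stopifnot(all(dim(fixed$data) == dim(moving$data)),
            fixed$voxel == moving$voxel)
  rf <- range(fixed$data); rm <- range(moving$data)
  if (rf[2] < rm[1] || rm[2] < rf[1])
    warning("fixed and moving intensity ranges do not overlap; ",
            "registration may stall")
  if (length(iterations) == 1) iterations <- rep(iterations, levels)
  if (length(iterations) != levels)
    stop("iterations must have one entry per level")
  dims0 <- dim(fixed$data)
  Fv <- as.numeric(cpp_gauss_smooth(as.numeric(fixed$data), dims0, presmooth))
  Mv <- as.numeric(cpp_gauss_smooth(as.numeric(moving$data), dims0, presmooth))
  # pyramid, coarsest first
  pyr <- list(list(f = Fv, m = Mv, dims = dims0, voxel = fixed$voxel))
  for (l in seq_len(levels - 1)) {
    prev <- pyr[[1]]
    dn_f <- cpp_downsample2(prev$f, prev$dims)
    dn_m <- cpp_downsample2(prev$m, prev$dims)
    pyr <- c(list(list(f = as.numeric(dn_f$volume), m = as.numeric(dn_m$volume),
                       dims = dn_f$dims, voxel = prev$voxel * 2)), pyr)
  }
  field <- NULL
  hist <- list()
  for (l in seq_along(pyr)) {
    lev <- pyr[[l]]
    if (is.null(field)) {
      init <- numeric(prod(lev$dims) * 3)
    } else {
      init <- unlist(lapply(1:3, function(c2)
        cpp_resample(field[, c2], prev_dims, lev$dims)))
      dim(init) <- NULL
    }
    res <- cpp_demons_level(lev$f, lev$m, init, lev$dims, lev$voxel,
                            iterations[l], sigma_fluid, sigma_diff, max_step)
    field <- matrix(res$field, ncol = 3)
    prev_dims <- lev$dims
    hist[[l]] <- res$residual
  }
  motion_vector_field(array(field, dim = c(dims0, 3)), fixed$voxel,
                      fixed$origin,
                      list(levels = levels, iterations = iterations,
                           sigma_fluid = sigma_fluid, sigma_diff = sigma_diff,
                           presmooth = presmooth, residual_history = hist))
}

#' Estimate adjacent-phase motion fields for a cyclic series
#'
#' Registers phase i (fixed) to phase i+1 (moving) for every i, wrapping at
#' the end, so field i samples the next phase from phase-i coordinates.
#'
#' @param phases a \code{volume4d}; @param ... passed to
#'   \code{\link{demons_register}}.
#' @export
estimate_cycle_fields <- function(phases, ...) {
  vols <- phases$volumes
  n <- length(vols)
  lapply(seq_len(n), function(i)
    demons_register(vols[[i]], vols[[if (i == n) 1 else i + 1]], ...))
}

compose_chain <- function(fields) {
  out <- fields[[1]]
  for (i in seq_along(fields)[-1]) out <- compose_fields(out, fields[[i]])
  out
}

#' Enforce loop closure of cyclic motion fields
#'
#' Cardiac motion returns to the same state after a complete cycle, so the
#' composition of all adjacent-phase fields around the loop must be the
#' identity. The loop residual is measured by composing the N fields in
#' cycle order; the correction subtracts 1/N of the residual from every
#' field (damped to keep the first-order correction stable on rough
#' fields) and iterates until the maximum residual displacement is below
#' \code{tol_vox} voxels, keeping the best iterate seen.
#'
#' @param fields list of \code{motion_vector_field}s forming a full cycle.
#' @param tol_vox loop-closure tolerance (voxels).
#' @param max_iter maximum correction sweeps.
#' @param damping fraction of the distributed residual applied per sweep.
#' @return list of corrected fields with residuals in attributes
#'   \code{residual_before} / \code{residual_after} (voxels).
#' @export
enforce_cyclicity <- function(fields, tol_vox = 0.1, max_iter = 25,
                              damping = 0.7) {
  n <- length(fields)
  loop_res <- function(fl) {
    L <- compose_chain(fl)
    list(field = L, max_vox = max_displacement_vox(L))
  }
  r0 <- loop_res(fields)
  res <- r0
  best <- fields
  best_res <- r0$max_vox
  it <- 0
  while (res$max_vox > tol_vox && it < max_iter) {
    corr <- res$field$u * (damping / n)
    fields <- lapply(fields, function(f) {
      f$u <- f$u - corr
      f
    })
    res <- loop_res(fields)
    if (res$max_vox < best_res) {
      best <- fields
      best_res <- res$max_vox
    }
    it <- it + 1
  }
  if (best_res > tol_vox)
    stop(sprintf(paste0("cyclicity correction did not converge: residual ",
                        "%.3f voxels after %d sweeps"), best_res, it))
  attr(best, "residual_before") <- r0$max_vox
  attr(best, "residual_after") <- best_res
  attr(best, "sweeps") <- it
  best
}

#' Motion-compensated superposition
#'
#' Warps every phase volume of a cyclic series to the reference phase by
#' composing adjacent-phase fields along the shorter arc of the cycle
#' (inverting fields where the short arc runs against the estimation
#' direction) and averages the warped volumes. With N phases the result
#' keeps the temporal resolution of a single gated phase at roughly
#' 1/sqrt(N) of its noise. The same machinery compensates any cyclic phase
#' dimension; feeding a respiratory-phase series at a fixed cardiac phase
#' yields the optional cross-respiratory second pass.
#'
#' @param phases a \code{volume4d}; @param fields cyclicity-corrected list
#'   of adjacent-phase fields; @param reference_bin reference phase index.
#' @return a \code{ct_volume} with provenance tag \code{MoCo}.
#' @export
motion_compensate <- function(phases, fields, reference_bin = 1) {
  vols <- phases$volumes
  n <- length(vols)
  if (length(fields) != n) stop("need one field per phase")
  if (reference_bin < 1 || reference_bin > n) stop("invalid reference_bin")
  acc <- vols[[reference_bin]]$data
  for (j in seq_len(n)[-reference_bin]) {
    fwd <- (j - reference_bin) %% n
    bwd <- n - fwd
    if (fwd <= bwd) {
      idx <- ((reference_bin - 1 + seq_len(fwd) - 1) %% n) + 1
      chain <- compose_chain(fields[idx])
    } else {
      idx <- ((reference_bin - 1 - seq_len(bwd)) %% n) + 1
      chain <- compose_chain(lapply(fields[idx], invert_field))
    }
    acc <- acc + warp_volume(vols[[j]], chain)$data
  }
  out <- vols[[reference_bin]]
  out$data <- acc / n
  out$provenance <- list(tag = "MoCo", reference_bin = reference_bin,
                         n_phases = n,
                         frame_counts = phases$frame_counts)
  out
}

#' Jacobian determinant of a displacement field
#' @param field a \code{motion_vector_field}.
#' @return 3D array of determinants of \code{I + du/dx}.
#' @export
field_jacobian <- function(field) {
  d <- field_dims(field)
  array(cpp_jacobian_det(as.numeric(field$u), d, field$voxel), dim = d)
}

#' Write a displacement field as multi-component NIfTI
#' @param field a \code{motion_vector_field}; @param path output path.
#' @export
write_field <- function(field, path) {
  img <- RNifti::asNifti(field$u)
  img <- RNifti::`pixdim<-`(img, c(rep(field$voxel, 3), 1))
  RNifti::writeNifti(img, path)
  invisible(path)
}
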