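#' Cone-beam scan geometry
#'
#' System constants of the circular cone-beam acquisition. Defaults follow
#' the full-scale protocol of the micro-CT system this package emulates:
#' source-isocenter distance 90 mm, source-detector distance 590 mm,
#' detector pixels of 4 x 74.8 um (4x4 binning), 86 frames/s, 10 s per
#' rotation, 300 s total scan, 5000 mGy nominal dose for the full scan.
#'
#' @param R_F source-isocenter distance, mm.
#' @param R_FD source-detector distance, mm.
#' @param detector_pixel_mm square detector pixel pitch, mm.
#' @param n_rows,n_cols detector size in pixels.
#' @param framerate frames per second.
#' @param rotation_time seconds per revolution.
#' @param scan_duration total scan time, s.
#' @param nominal_full_dose_mGy dose corresponding to the full scan.
#' @param photons_per_frame photon budget I0 per detector pixel per frame at
#'   full dose (monochromatic effective-energy model).
#' @return object of class \code{scan_geometry}.
#' @export
scan_geometry <- function(R_F = 90, R_FD = 590,
                          detector_pixel_mm = 4 * 0.0748,
                          n_rows = 96, n_cols = 128,
                          framerate = 86, rotation_time = 10,
                          scan_duration = 300,
                          nominal_full_dose_mGy = 5000,
                          photons_per_frame = 1e5) {
  if (!(R_FD > R_F && R_F > 0)) stop("need R_FD > R_F > 0")
  if (detector_pixel_mm <= 0) stop("detector pixel must be positive")
  if (framerate * rotation_time < 4)
    stop("framerate x rotation_time below minimum angular sampling")
  g <- list(R_F = R_F, R_FD = R_FD, detector_pixel_mm = detector_pixel_mm,
            n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
            framerate = framerate, rotation_time = rotation_time,
            scan_duration = scan_duration,
            nominal_full_dose_mGy = nominal_full_dose_mGy,
            photons_per_frame = photons_per_frame)
  g$magnification <- R_FD / R_F
  g$fov_mm <- n_cols * detector_pixel_mm / g$magnification
  class(g) <- "scan_geometry"
  g
}

#' Desk-scale acquisition profile
#'
#' A reduced profile for desk-top simulation studies: 128x96 detector pixels
#' with the pitch rescaled to preserve a 12 mm field of view, the full
#' protocol's 86 fps and 10 s/rev rotation (so each revolution samples 860
#' distinct angles and intrinsic gating stays well-posed; a faster rotation
#' commensurate with the framerate would lock the angular schedule to a few
#' repeated angles), and a 60 s scan (5160 frames, 6 revolutions - long
#' enough that even a tenfold dose reduction leaves every joint gating bin
#' populated). Optional arguments shrink it further for quick tests. The
#' per-frame photon budget is raised relative to the full protocol so that
#' the desk scan carries the photon statistics of the full-dose 5 min
#' acquisition.
#'
#' @param n_cols,n_rows detector size; @param scan_duration seconds.
#' @param fov_mm transverse field of view at the isocenter.
#' @param rotation_time seconds per revolution.
#' @param photons_per_frame per-pixel photon budget per frame at full dose.
#' @param ... passed on to \code{scan_geometry}.
#' @export
desk_geometry <- function(n_cols = 128, n_rows = 96, scan_duration = 60,
                          fov_mm = 12, rotation_time = 10,
                          photons_per_frame = 1e6, ...) {
  pixel <- fov_mm * (590 / 90) / n_cols
  scan_geometry(detector_pixel_mm = pixel, n_rows = n_rows, n_cols = n_cols,
                framerate = 86, rotation_time = rotation_time,
                scan_duration = scan_duration,
                photons_per_frame = photons_per_frame, ...)
}

#' Acquisition timeline
#'
#' Per-frame timestamps and gantry angles of the continuous rotation:
#' \code{floor(framerate * scan_duration)} frames at 1/framerate spacing,
#' angle = 2 pi t / rotation_time (mod 2 pi).
#'
#' @param geometry a \code{scan_geometry}.
#' @export
make_timeline <- function(geometry) {
  nf <- floor(geometry$framerate * geometry$scan_duration)
  if (nf < 1) stop("scan duration too short: no frames")
  t <- (seq_len(nf) - 1) / geometry$framerate
  structure(list(index = seq_len(nf), time = t,
                 angle = (2 * pi * t / geometry$rotation_time) %% (2 * pi),
                 n_revolutions = geometry$scan_duration / geometry$rotation_time),
            class = "acq_timeline")
}

#' Analytic forward projection of one frame
#'
#' Exact line integrals through the compound-primitive phantom instantiated
#' at the frame timestamp (motion frozen at the frame midpoint; the finite
#' integration time of the real detector is not simulated unless
#' \code{supersample > 1} averages sub-frame instants).
#'
#' @param spec a \code{phantom_spec}; @param geometry a \code{scan_geometry}.
#' @param timeline an \code{acq_timeline}; @param frame_index 1-based index.
#' @param supersample number of sub-frame time samples to average.
#' @return matrix (n_rows x n_cols) of line integrals (dimensionless).
#' @export
forward_project <- function(spec, geometry, timeline, frame_index,
                            supersample = 1) {
  if (frame_index < 1 || frame_index > length(timeline$index))
    stop("frame_index out of range")
  t0 <- timeline$time[frame_index]
  dt <- 1 / geometry$framerate
  ts <- if (supersample > 1)
    t0 + (seq_len(supersample) - 0.5) / supersample * dt else t0
  acc <- NULL
  for (tt in ts) {
    st <- phantom_instantiate(spec, tt)
    ang <- (2 * pi * tt / geometry$rotation_time) %% (2 * pi)
    fr <- cpp_project_frame(st$primitives, ang, geometry$R_F, geometry$R_FD,
                            geometry$detector_pixel_mm, geometry$n_rows,
                            geometry$n_cols)
    acc <- if (is.null(acc)) fr else acc + fr
  }
  acc / length(ts)
}

#' Simulate a complete scan
#'
#' Projects every frame of the timeline and assembles a projection set.
#' The phantom is re-instantiated per frame; for a static spec (both motion
#' amplitudes zero) the instantiation is hoisted out of the loop.
#'
#' @inheritParams forward_project
#' @param verbose print progress.
#' @return a \code{projection_set}: frames array (rows x cols x n_frames),
#'   timeline, geometry, dose fraction and true phase track.
#' @export
simulate_scan <- function(spec, geometry, timeline = make_timeline(geometry),
                          verbose = FALSE) {
  nf <- length(timeline$index)
  frames <- array(0, dim = c(geometry$n_rows, geometry$n_cols, nf))
  static <- spec$ejection_amplitude == 0 && spec$resp_amplitude_mm == 0 &&
    spec$resp_ap_frac == 0
  st <- if (static) phantom_instantiate(spec, 0) else NULL
  for (f in seq_len(nf)) {
    if (!static) st <- phantom_instantiate(spec, timeline$time[f])
    frames[, , f] <- cpp_project_frame(st$primitives, timeline$angle[f],
                                       geometry$R_F, geometry$R_FD,
                                       geometry$detector_pixel_mm,
                                       geometry$n_rows, geometry$n_cols)
    if (verbose && f %% 500 == 0) message("frame ", f, "/", nf)
  }
  truth <- phantom_phases(spec, timeline$time)
  projection_set(frames, timeline, geometry, dose_fraction = 1,
                 true_phases = truth, spec = spec)
}

#' Projection set container
#'
#' Houses the post-log line-integral raw data together with its acquisition
#' timeline, geometry, dose bookkeeping and (for simulations) the ground
#' truth phase track.
#'
#' @param frames array (n_rows, n_cols, n_frames) of line integrals.
#' @param timeline an \code{acq_timeline}; @param geometry a
#'   \code{scan_geometry}; @param dose_fraction fraction of nominal dose.
#' @param noise_seed seed used when noise was applied (NA if noiseless).
#' @param true_phases optional simulator ground-truth phases.
#' @param spec optional generating \code{phantom_spec}.
#' @export
projection_set <- function(frames, timeline, geometry, dose_fraction = 1,
                           noise_seed = NA_integer_, true_phases = NULL,
                           spec = NULL) {
  stopifnot(length(dim(frames)) == 3)
  if (dim(frames)[3] != length(timeline$index))
    stop("frame count does not match timeline length")
  if (dose_fraction <= 0 || dose_fraction > 1)
    stop("dose_fraction must be in (0, 1]")
  if (any(!is.finite(frames))) stop("projections contain non-finite values")
  structure(list(frames = frames, timeline = timeline, geometry = geometry,
                 dose_fraction = dose_fraction, noise_seed = noise_seed,
                 true_phases = true_phases, spec = spec),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<projection_set> %d frames of %dx%d, dose fraction %.3g%s\n",
              d[3], d[1], d[2], x$dose_fraction,
              if (is.na(x$noise_seed)) " (noiseless)" else ""))
  invisible(x)
}

#' Apply dose-scaled photon noise
#'
#' Transmitted counts are Poisson with mean
#' \code{I0 * dose_fraction * exp(-q)} per pixel and the post-log data are
#' returned. Counts are floored at 0.5 before the log (photon-starvation
#' guard); a mean air-count below 10 triggers a warning since the log
#' transform is biased in that regime.
#'
#' @param ps a \code{projection_set} with noiseless line integrals.
#' @param dose_fraction fraction of the per-frame photon budget.
#' @param seed RNG seed (frames with equal seeds are bit-identical).
#' @export
apply_noise <- function(ps, dose_fraction = 1, seed = 1L) {
  if (dose_fraction <= 0 || dose_fraction > 1)
    stop("dose_fraction must be in (0, 1]")
  I0 <- ps$geometry$photons_per_frame * dose_fraction
  if (I0 < 10) warning("mean air counts below 10: log-transform bias regime")
  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  counts <- stats::rpois(length(ps$frames), lambda = I0 * exp(-ps$frames))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  q <- array(log(I0) - log(pmax(counts, 0.5)), dim = dim(ps$frames))
  out <- ps
  out$frames <- q
  out$dose_fraction <- ps$dose_fraction * dose_fraction
  out$noise_seed <- as.integer(seed)
  out
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

#' Thin a projection set to a fraction of its frames
#'
#' Uniform frame thinning (the default dose-reduction mechanism): keeps an
#' evenly spaced subset of frames, preserving angular coverage across the
#' revolutions.
#'
#' @param ps a \code{projection_set}; @param fraction fraction to keep.
#' @param offset starting offset (frames), e.g. for seed-controlled variants.
#' @export
thin_frames <- function(ps, fraction, offset = 0) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  nf <- dim(ps$frames)[3]
  keep <- unique(pmin(nf, 1 + offset + round(seq(0, nf - 1, by = 1 / fraction))))
  subset_frames(ps, keep)
}

#' Subset a projection set by frame indices
#' @param ps a \code{projection_set}; @param idx frame indices to keep.
#' @export
subset_frames <- function(ps, idx) {
  out <- ps
  out$frames <- ps$frames[, , idx, drop = FALSE]
  out$timeline <- structure(list(index = seq_along(idx),
                                 time = ps$timeline$time[idx],
                                 angle = ps$timeline$angle[idx],
                                 n_revolutions = ps$timeline$n_revolutions),
                            class = "acq_timeline")
  if (!is.null(ps$true_phases))
    out$true_phases <- lapply(ps$true_phases, `[`, idx)
  out
}

#' Voxelized ray-marching projection (cross-check oracle)
#'
#' Projects a voxelized phantom state by trilinear ray marching; used as an
#' independent low-resolution check of the analytic projector.
#'
#' @param vol a \code{ct_volume}; @param geometry a \code{scan_geometry}.
#' @param angle gantry angle, rad; @param step march step, mm.
#' @export
voxel_project <- function(vol, geometry, angle, step = NULL) {
  if (is.null(step)) step <- vol$voxel / 2
  cpp_voxel_project_frame(as.numeric(vol$data), dim(vol$data), vol$voxel,
                          vol$origin, angle, geometry$R_F, geometry$R_FD,
                          geometry$detector_pixel_mm, geometry$n_rows,
                          geometry$n_cols, step)
}

#' Persist / load a projection set
#'
#' Native serialization of the package (frames, timeline, geometry,
#' provenance in one file); the reader re-validates the container
#' invariants on load.
#'
#' @param ps a \code{projection_set}; @param path file path (.rds).
#' @export
write_projections <- function(ps, path) {
  saveRDS(ps, path)
  invisible(path)
}

#' @rdname write_projections
#' @export
read_projections <- function(path) {
  ps <- readRDS(path)
  projection_set(ps$frames, ps$timeline, ps$geometry, ps$dose_fraction,
                 ps$noise_seed, ps$true_phases, ps$spec)
}
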