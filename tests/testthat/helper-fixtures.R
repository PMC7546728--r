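# Shared fixtures, built lazily and cached for the whole test run. All
# simulations are desk-scale reductions of the full acquisition protocol
# (smaller detector, shorter scans) so the complete suite runs on one CPU.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- build()
  .fx_cache[[name]]
}

# single-primitive water cylinder (radius 3 mm, mu = 0.02/mm along z)
cyl_prim <- function() matrix(c(1, 0, 0, -8, 0, 0, 8, 3, 0.02, 1), nrow = 1)

project_prims <- function(prim, geom, timeline) {
  nf <- length(timeline$index)
  frames <- array(0, dim = c(geom$n_rows, geom$n_cols, nf))
  for (f in seq_len(nf))
    frames[, , f] <- mococt:::cpp_project_frame(
      prim, timeline$angle[f], geom$R_F, geom$R_FD, geom$detector_pixel_mm,
      geom$n_rows, geom$n_cols)
  projection_set(frames, timeline, geom)
}

# 1720-frame multi-revolution scan of the static cylinder (86 angles/rev)
fx_cyl_scan <- function() fx("cyl_scan", function() {
  geom <- scan_geometry(detector_pixel_mm = 12 * (590 / 90) / 64,
                        n_rows = 24, n_cols = 64, framerate = 86,
                        rotation_time = 1, scan_duration = 20,
                        photons_per_frame = 1e5)
  ps <- project_prims(cyl_prim(), geom, make_timeline(geom))
  grid <- recon_grid(c(48, 48, 10), 12 / 64)
  roi <- sphere_roi(empty_volume(grid), c(0, 0, 0), 1.5)
  roi[, , c(1:2, 9:10)] <- FALSE
  list(ps = ps, grid = grid, roi = roi, ref = fdk(ps, grid))
})

# 240 distinct angles, thin detector: for the 2D fan-beam oracle comparison
fx_fan_scan <- function() fx("fan_scan", function() {
  geom <- scan_geometry(detector_pixel_mm = 12 * (590 / 90) / 64,
                        n_rows = 5, n_cols = 64, framerate = 240,
                        rotation_time = 1, scan_duration = 1)
  list(ps = project_prims(cyl_prim(), geom, make_timeline(geom)),
       geom = geom)
})

# dynamic desk scenario: 90 s, 64x48 detector, intrinsic gating
fx_dyn <- function() fx("dyn", function() {
  spec <- desk_phantom_spec()
  geom <- desk_geometry(n_cols = 64, n_rows = 48, scan_duration = 90,
                        photons_per_frame = 1e6)
  ps <- simulate_scan(spec, geom)
  psn <- apply_noise(ps, 1, seed = 6L)
  track <- extract_gating_signals(psn)
  list(spec = spec, geom = geom, ps = ps, psn = psn, track = track)
})

# phase-correlated series + cyclic fields + MoCo in the end-expiration bin
fx_moco <- function() fx("moco", function() {
  d <- fx_dyn()
  gspec <- gating_spec()
  grid <- recon_grid(48, 0.2)
  series <- suppressWarnings(
    reconstruct_phase_series(d$psn, d$track, gspec, grid, resp_bin = 3))
  fields <- enforce_cyclicity(estimate_cycle_fields(series))
  moco <- motion_compensate(series, fields, reference_bin = 1)
  rois <- mococt:::sweep_rois(d$ps, d$track, gspec, grid, 1, 3)
  bins <- suppressWarnings(assign_bins(d$track, gspec))
  pc0 <- suppressWarnings(fdk_gated(d$ps, bins$joint_mask[, 1, 3], grid))
  list(gspec = gspec, grid = grid, series = series, fields = fields,
       moco = moco, state = rois$state, rois = rois, pc_noiseless = pc0)
})

# full-protocol-rotation gating scenario at the headline 600 bpm / 300 rpm
fx_gat600 <- function() fx("gat600", function() {
  spec <- phantom_spec(heart_rate = 600, resp_rate = 300)
  geom <- desk_geometry(n_cols = 64, n_rows = 48, scan_duration = 30,
                        photons_per_frame = 1e5)
  ps <- simulate_scan(spec, geom)
  psn <- apply_noise(ps, 1, seed = 5L)
  list(ps = ps, psn = psn, track = extract_gating_signals(psn))
})

# static-heart scan with a 100% respiratory window: the photon budget of
# f_MoCo (10 cardiac bins averaged) then equals that of f_Std exactly
fx_moco_static <- function() fx("moco_static", function() {
  spec <- desk_phantom_spec(ejection_amplitude = 0, resp_amplitude_mm = 0,
                            resp_ap_frac = 0)
  geom <- desk_geometry(n_cols = 64, n_rows = 48, scan_duration = 20,
                        photons_per_frame = 2e5)
  ps <- simulate_scan(spec, geom)
  gspec <- gating_spec(n_resp_bins = 1, resp_width = 1)
  grid <- recon_grid(48, 0.2)
  track <- phase_track(ps$timeline$time,
                       (ps$timeline$time * 587 / 60) %% 1,
                       (ps$timeline$time * 283 / 60) %% 1)
  chain <- function(seed) {
    psn <- apply_noise(ps, 1, seed = seed)
    series <- suppressWarnings(
      reconstruct_phase_series(psn, track, gspec, grid, resp_bin = 1))
    fields <- enforce_cyclicity(estimate_cycle_fields(series))
    list(std = fdk(psn, grid), pc = series$volumes[[1]],
         moco = motion_compensate(series, fields, 1))
  }
  roi <- sphere_roi(empty_volume(grid), c(-3.2, -2.2, -2.5), 1.0)
  list(ps = ps, grid = grid, track = track, gspec = gspec, roi = roi,
       a = chain(101L), b = chain(102L))
})

# noise sd of the difference of two realizations (isolates photon noise
# from structured artifacts common to both)
noise_sd_pair <- function(va, vb, roi) stats::sd((va$data - vb$data)[roi]) / sqrt(2)

# Independent 2D flat-detector fan-beam FBP (direct-space ramp convolution,
# own interpolation): oracle for the FDK central slice in the cone -> 0
# configuration.
fan_fbp_2d <- function(sino, angles, R_F, du, nx, voxel) {
  nc <- ncol(sino)
  u <- (seq_len(nc) - (nc + 1) / 2) * du
  cw <- R_F / sqrt(R_F^2 + u^2)
  offs <- -(nc - 1):(nc - 1)
  hk <- ifelse(offs == 0, 1 / (4 * du^2),
               ifelse(offs %% 2 != 0, -1 / (pi^2 * offs^2 * du^2), 0))
  filt <- matrix(0, nrow(sino), nc)
  for (a in seq_len(nrow(sino))) {
    p <- sino[a, ] * cw
    for (j in seq_len(nc))
      filt[a, j] <- sum(p * hk[(j - seq_len(nc)) + nc]) * du
  }
  xs <- (seq_len(nx) - (nx + 1) / 2) * voxel
  img <- matrix(0, nx, nx)
  dth <- 2 * pi / nrow(sino)
  for (a in seq_len(nrow(sino))) {
    th <- angles[a]
    e <- c(cos(th), sin(th)); uh <- c(-sin(th), cos(th))
    for (iy in seq_len(nx)) for (ix in seq_len(nx)) {
      x <- c(xs[ix], xs[iy])
      U <- R_F / (R_F - sum(x * e))
      iu <- U * sum(x * uh) / du + (nc + 1) / 2
      i0 <- floor(iu)
      if (i0 >= 1 && i0 < nc) {
        f <- iu - i0
        img[ix, iy] <- img[ix, iy] +
          U^2 * ((1 - f) * filt[a, i0] + f * filt[a, i0 + 1]) * dth / 2
      }
    }
  }
  img
}

# full-width at half maximum of a profile across a thin bright structure
profile_fwhm <- function(vol, p0, dir, half_mm, step_mm) {
  pr <- sample_line(vol, p0, dir, half_mm, step_mm)
  v <- pr$value - min(pr$value, na.rm = TRUE)
  above <- which(v >= max(v, na.rm = TRUE) / 2)
  (max(above) - min(above)) * step_mm
}
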