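test_that("timeline matches the acquisition protocol", {
  tl <- make_timeline(scan_geometry())
  expect_equal(length(tl$index), 25800)          # floor(86 fps x 300 s)
  expect_equal(tl$n_revolutions, 30)
  expect_equal(tl$angle[1], 0)
  k5 <- which(tl$time == 5)                      # half a 10 s revolution
  expect_equal(tl$angle[k5], pi)
  expect_true(all(diff(tl$time) > 0))
  expect_equal(diff(tl$time)[1], 1 / 86)
  expect_error(make_timeline(scan_geometry(scan_duration = 0.001)), "frames")
})

test_that("geometry invariants are enforced", {
  expect_error(scan_geometry(R_F = 600), "R_FD")
  expect_error(scan_geometry(detector_pixel_mm = 0), "pixel")
  expect_equal(scan_geometry()$magnification, 590 / 90)
})

test_that("central ray through a sphere integrates to diameter times mu", {
  prim <- matrix(c(0, 0, 0, 0, 2, 2, 2, 0, 0.02, 1), nrow = 1)
  g <- scan_geometry(n_rows = 33, n_cols = 65, detector_pixel_mm = 0.3)
  fr <- mococt:::cpp_project_frame(prim, 0, g$R_F, g$R_FD,
                                   g$detector_pixel_mm, 33, 65)
  expect_equal(fr[17, 33], 4 * 0.02, tolerance = 1e-10)
})

test_that("off-centre rays match the closed-form chord length", {
  R <- 2; mu <- 0.02
  prim <- matrix(c(0, 0, 0, 0, R, R, R, 0, mu, 1), nrow = 1)
  g <- scan_geometry(n_rows = 3, n_cols = 129, detector_pixel_mm = 0.3)
  fr <- mococt:::cpp_project_frame(prim, 0, g$R_F, g$R_FD,
                                   g$detector_pixel_mm, 3, 129)
  # distance of pixel-j ray from the sphere centre (at the isocenter)
  for (j in c(45, 55, 65, 75, 85)) {
    u <- (j - 65) * 0.3
    # perpendicular distance from the sphere centre (origin) to the ray
    # through source S and detector point P
    S <- c(g$R_F, 0); P <- c(g$R_F - g$R_FD, u)
    d <- abs(S[1] * P[2] - S[2] * P[1]) / sqrt(sum((P - S)^2))
    chord <- if (d < R) 2 * sqrt(R^2 - d^2) else 0
    expect_equal(fr[2, j], chord * mu, tolerance = 1e-8)
  }
})

test_that("a centred sphere subtends detector width by the magnification", {
  rho <- 0.5
  prim <- matrix(c(0, 0, 0, 0, rho, rho, rho, 0, 0.02, 1), nrow = 1)
  g <- scan_geometry(n_rows = 3, n_cols = 257, detector_pixel_mm = 0.05)
  fr <- mococt:::cpp_project_frame(prim, 0.4, g$R_F, g$R_FD,
                                   g$detector_pixel_mm, 3, 257)
  nz <- range(which(fr[2, ] > 0))
  width <- (diff(nz) + 1) * 0.05
  expect_equal(width, 2 * rho * g$R_FD / g$R_F, tolerance = 0.05)
})

test_that("projection is linear in mu and additive over disjoint primitives", {
  s1 <- matrix(c(0, -1.5, 0, 0, 0.8, 0.8, 0.8, 0, 0.02, 1), nrow = 1)
  s2 <- matrix(c(0, 1.5, 0.5, 0, 0.8, 0.8, 0.8, 0, 0.013, 1), nrow = 1)
  s1x2 <- s1; s1x2[9] <- 0.04
  g <- scan_geometry(n_rows = 17, n_cols = 65, detector_pixel_mm = 0.4)
  pr <- function(p) mococt:::cpp_project_frame(p, 0.9, g$R_F, g$R_FD,
                                               g$detector_pixel_mm, 17, 65)
  expect_equal(pr(s1x2), 2 * pr(s1), tolerance = 1e-12)
  expect_equal(pr(rbind(s1, s2)), pr(s1) + pr(s2), tolerance = 1e-12)
})

test_that("empty phantom projects to zero and static frames repeat per rotation", {
  g <- scan_geometry(n_rows = 5, n_cols = 17, detector_pixel_mm = 1)
  empty <- matrix(numeric(0), nrow = 0, ncol = 10)
  fr <- mococt:::cpp_project_frame(empty, 0.3, g$R_F, g$R_FD, 1, 5, 17)
  expect_true(all(fr == 0))
  cyl <- fx_cyl_scan()
  # 86 frames per revolution at this profile: same angle, same projection
  expect_equal(cyl$ps$frames[, , 1], cyl$ps$frames[, , 87])
  expect_equal(cyl$ps$timeline$angle[1], cyl$ps$timeline$angle[87])
})

test_that("photon noise follows the delta-method variance and is seeded", {
  g <- scan_geometry(detector_pixel_mm = 1, n_rows = 10, n_cols = 10,
                     framerate = 100, rotation_time = 1, scan_duration = 1,
                     photons_per_frame = 1e4)
  ps <- projection_set(array(0, dim = c(10, 10, 100)), make_timeline(g), g)
  noisy <- apply_noise(ps, 1, seed = 7L)
  v <- stats::var(as.numeric(noisy$frames))
  expect_equal(v, 1e-4, tolerance = 0.05)       # 1/(I0 f) in air
  half <- apply_noise(ps, 0.5, seed = 8L)
  expect_equal(stats::var(as.numeric(half$frames)) / v, 2, tolerance = 0.05)
  expect_identical(apply_noise(ps, 1, seed = 42L)$frames,
                   apply_noise(ps, 1, seed = 42L)$frames)
  # infinite-dose limit returns the input
  g2 <- g; g2$photons_per_frame <- 1e12
  ps2 <- ps; ps2$geometry <- g2
  expect_lt(max(abs(apply_noise(ps2, 1, seed = 1L)$frames - ps$frames)), 1e-4)
  expect_error(apply_noise(ps, 1.5), "dose_fraction")
  expect_warning(apply_noise(ps, 5e-4, seed = 1L), "counts")
})

test_that("frame thinning keeps the requested evenly spaced fraction", {
  cyl <- fx_cyl_scan()
  th <- thin_frames(cyl$ps, 0.1)
  expect_equal(dim(th$frames)[3] / dim(cyl$ps$frames)[3], 0.1,
               tolerance = 0.01)
  expect_true(all(diff(th$timeline$time) > 0))
  expect_error(thin_frames(cyl$ps, 0), "fraction")
})

test_that("projection sets survive a save/load round trip with validation", {
  cyl <- fx_cyl_scan()
  small <- subset_frames(cyl$ps, 1:10)
  path <- tempfile(fileext = ".rds")
  write_projections(small, path)
  back <- read_projections(path)
  expect_equal(back$frames, small$frames)
  expect_equal(back$timeline$angle, small$timeline$angle)
  bad <- small
  bad$frames <- bad$frames[, , 1:5]
  saveRDS(bad, path)
  expect_error(read_projections(path), "frame count")
})

test_that("analytic projector agrees with the voxel ray-marching oracle", {
  spec <- phantom_spec(ejection_amplitude = 0, resp_amplitude_mm = 0,
                       resp_ap_frac = 0)
  st <- phantom_instantiate(spec, 0)
  grid <- recon_grid(c(88, 80, 104), 0.15)
  vol <- voxelize_phantom(st, grid)
  g <- scan_geometry(detector_pixel_mm = 12 * (590 / 90) / 48,
                     n_rows = 32, n_cols = 48)
  tl <- make_timeline(g)
  exact <- forward_project(spec, g, tl, 500)
  march <- voxel_project(vol, g, tl$angle[500], step = 0.075)
  sig <- exact > 0.1 * max(exact)
  rel_rms <- sqrt(mean((exact[sig] - march[sig])^2)) / mean(exact[sig])
  expect_lt(rel_rms, 0.05)
})
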