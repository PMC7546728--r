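test_that("all-zero projections reconstruct to an all-zero volume", {
  g <- scan_geometry(detector_pixel_mm = 1, n_rows = 8, n_cols = 16,
                     framerate = 90, rotation_time = 1, scan_duration = 1)
  ps <- projection_set(array(0, dim = c(8, 16, 90)), make_timeline(g), g)
  vol <- fdk(ps, recon_grid(c(12, 12, 4), 0.5))
  expect_true(all(vol$data == 0))
})

test_that("a static water cylinder reconstructs to its true attenuation", {
  cyl <- fx_cyl_scan()
  s <- roi_stats(cyl$ref, cyl$roi, hu = FALSE)
  expect_lt(abs(s$mean - 0.02) / 0.02, 0.03)
})

test_that("central slice matches an independent 2D fan-beam FBP oracle", {
  fan <- fx_fan_scan()
  ps <- fan$ps
  grid <- recon_grid(c(48, 48, 3), 12 / 64)
  vol <- fdk(ps, grid, apodization = "ramlak")
  du <- fan$geom$detector_pixel_mm * fan$geom$R_F / fan$geom$R_FD
  sino <- t(sapply(seq_len(240), function(f) ps$frames[3, , f]))
  oracle <- fan_fbp_2d(sino, ps$timeline$angle, fan$geom$R_F, du, 48, 12 / 64)
  roi <- sqrt(outer((1:48 - 24.5)^2, (1:48 - 24.5)^2, "+")) < 12
  expect_lt(max(abs(vol$data[, , 2][roi] - oracle[roi])) / 0.02, 0.01)
})

test_that("insufficient angular coverage raises an informative error", {
  g <- scan_geometry(detector_pixel_mm = 1, n_rows = 8, n_cols = 16,
                     framerate = 90, rotation_time = 10, scan_duration = 1)
  ps <- projection_set(array(0, dim = c(8, 16, 90)), make_timeline(g), g)
  expect_error(fdk(ps, recon_grid(c(12, 12, 4), 0.5)), "angular coverage")
  expect_error(fdk(subset_frames(ps, 1), recon_grid(c(12, 12, 4), 0.5)),
               "two frames")
})

test_that("reconstruction is linear in the projection data", {
  fan <- fx_fan_scan()
  ps <- subset_frames(fan$ps, seq(1, 240, by = 2))
  grid <- recon_grid(c(24, 24, 3), 0.4)
  v1 <- fdk(ps, grid)
  ps2 <- ps; ps2$frames <- 2 * ps$frames
  ps3 <- ps; ps3$frames <- 3 * ps$frames
  v2 <- fdk(ps2, grid); v3 <- fdk(ps3, grid)
  expect_equal(v3$data, v1$data + v2$data, tolerance = 1e-10)
})

test_that("gated FDK with the full mask equals the standard FDK", {
  cyl <- fx_cyl_scan()
  gat <- suppressWarnings(
    fdk_gated(cyl$ps, rep(TRUE, dim(cyl$ps$frames)[3]), cyl$grid))
  expect_equal(gat$data, cyl$ref$data, tolerance = 1e-14)
})

test_that("density re-weighting keeps sparse gated values unbiased", {
  cyl <- fx_cyl_scan()
  set.seed(1)
  mask <- stats::runif(dim(cyl$ps$frames)[3]) < 0.025
  gat <- suppressWarnings(fdk_gated(cyl$ps, mask, cyl$grid))
  full <- roi_stats(cyl$ref, cyl$roi, hu = FALSE)$mean
  sparse <- roi_stats(gat, cyl$roi, hu = FALSE)$mean
  expect_lt(abs(sparse - full) / full, 0.03)
  expect_error(fdk_gated(cyl$ps, rep(FALSE, dim(cyl$ps$frames)[3]),
                         cyl$grid), "masked out")
})

test_that("gated noise scales as one over the square root of the fraction", {
  cyl <- fx_cyl_scan()
  noisy <- apply_noise(cyl$ps, 1, seed = 3L)
  nf <- dim(cyl$ps$frames)[3]
  s_full <- stats::sd((fdk(noisy, cyl$grid)$data - cyl$ref$data)[cyl$roi])
  for (p in c(0.025, 0.1)) {
    keep <- unique(round(seq(1, nf, by = 1 / p)))
    m <- rep(FALSE, nf); m[keep] <- TRUE
    g0 <- suppressWarnings(fdk_gated(cyl$ps, m, cyl$grid))
    gn <- suppressWarnings(fdk_gated(noisy, m, cyl$grid))
    s_g <- stats::sd((gn$data - g0$data)[cyl$roi])
    expect_equal(s_g / s_full, 1 / sqrt(mean(m)), tolerance = 0.15)
  }
})

test_that("reconstruction noise scales as one over the square root of dose", {
  cyl <- fx_cyl_scan()
  fracs <- c(1, 0.5, 0.25, 0.125)
  sds <- vapply(seq_along(fracs), function(i) {
    noisy <- apply_noise(cyl$ps, fracs[i], seed = 10L + i)
    stats::sd((fdk(noisy, cyl$grid)$data - cyl$ref$data)[cyl$roi])
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(sds) ~ log(fracs)))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.05)
})

test_that("very sparse gating raises structured artifact power monotonically", {
  cyl <- fx_cyl_scan()
  nf <- dim(cyl$ps$frames)[3]
  energy <- vapply(c(0.025, 0.01, 0.004), function(p) {
    keep <- unique(round(seq(1, nf, by = 1 / p)))
    m <- rep(FALSE, nf); m[keep] <- TRUE
    g <- suppressWarnings(fdk_gated(cyl$ps, m, cyl$grid))
    stats::sd((g$data - cyl$ref$data)[cyl$roi])
  }, numeric(1))
  expect_true(all(diff(energy) > 0))   # artifact power grows with 1/p
})

test_that("a static phantom yields ten mutually consistent phase volumes", {
  ms <- fx_moco_static()
  series <- suppressWarnings(
    reconstruct_phase_series(ms$ps, ms$track, ms$gspec, ms$grid,
                             resp_bin = 1))
  expect_equal(sum(series$frame_counts), dim(ms$ps$frames)[3])
  ref <- series$volumes[[1]]$data
  scale <- diff(range(ref))
  for (k in 2:10)
    expect_lt(mean(abs(series$volumes[[k]]$data - ref)) / scale, 0.02)
})

test_that("dynamic phase volumes track the ventricular cycle", {
  mo <- fx_moco()
  series <- mo$series
  mu_mid <- hu_to_mu((50 + 600) / 2)
  blood <- vapply(series$volumes, function(v) sum(v$data > mu_mid),
                  numeric(1))
  # systole occupies a contiguous ~1/3 of the cycle: the fullest bin must
  # clearly exceed the emptiest, and the two extremes sit in different
  # halves of the contraction waveform
  expect_gt(max(blood) / min(blood), 1.3)
  d <- fx_dyn()
  bins <- suppressWarnings(assign_bins(d$track, mo$gspec))
  expect_equal(sum(series$frame_counts), sum(bins$resp_mask[, 3]))
})
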