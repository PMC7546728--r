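test_that("ROI statistics match direct computation", {
  set.seed(5)
  grid <- recon_grid(20, 0.2)
  v <- new_volume(array(hu_to_mu(stats::rnorm(20^3, 100, 50)),
                        dim = rep(20, 3)), 0.2, grid$origin)
  roi <- sphere_roi(v, c(0, 0, 0), 1.5)
  s <- roi_stats(v, roi)
  expect_equal(s$sd, 50, tolerance = 0.05 * 50)
  const <- v; const$data[] <- hu_to_mu(100)
  expect_equal(roi_stats(const, roi)$sd, 0)
  # voxel-count-weighted mean over two disjoint ROIs
  roi2 <- sphere_roi(v, c(1.5, 1.5, 0), 0.8) & !roi
  both <- roi | roi2
  m <- roi_stats(v, both)$mean
  m1 <- roi_stats(v, roi); m2 <- roi_stats(v, roi2)
  expect_equal(m, (m1$mean * m1$n + m2$mean * m2$n) / (m1$n + m2$n))
  expect_error(roi_stats(v, array(FALSE, dim = rep(20, 3))), "empty")
})

test_that("CNR matches its definition and the Rose criterion", {
  grid <- recon_grid(16, 0.2)
  set.seed(8)
  bgv <- stats::rnorm(16^3, 0, 75)
  v <- new_volume(array(hu_to_mu(bgv), dim = rep(16, 3)), 0.2, grid$origin)
  sig <- array(FALSE, dim = rep(16, 3)); sig[7:10, 7:10, 7:10] <- TRUE
  bg <- !sig
  v$data[sig] <- hu_to_mu(mean(bgv[bg]) + 300)
  out <- cnr(v, sig, bg)
  # independent two-pass recomputation from raw voxels
  hu <- mu_to_hu(v$data)
  manual <- (mean(hu[sig]) - mean(hu[bg])) / stats::sd(hu[bg])
  expect_equal(out$cnr, manual)
  expect_equal(out$cnr, 300 / stats::sd(hu[bg]), tolerance = 0.05)
  expect_true(out$detectable == (out$cnr >= 4))
  same <- v; same$data[] <- hu_to_mu(100)
  expect_error(cnr(same, sig, bg), "zero variance")
  noisy0 <- v; noisy0$data[sig] <- v$data[bg][seq_len(sum(sig))]
  expect_lt(abs(cnr(noisy0, sig, bg)$cnr), 0.5)
})

test_that("sliding-thin-slab MIP equals the brute-force maximum", {
  set.seed(9)
  grid <- recon_grid(16, 0.2)
  v <- new_volume(array(stats::runif(16^3), dim = rep(16, 3)), 0.2,
                  grid$origin)
  out <- sts_mip(v, axis = 3, slab_mm = 0.2 * 4)
  expect_equal(dim(out)[3], 13)
  for (p in c(1, 5, 13)) {
    brute <- apply(v$data[, , p:(p + 3)], c(1, 2), max)
    expect_equal(out[, , p], brute)
  }
  # pointwise >= each constituent slice, slab of one returns the slice
  expect_true(all(out[, , 1] >= v$data[, , 2]))
  one <- sts_mip(v, axis = 3, slab_mm = 0.2)
  expect_equal(one[, , 7], v$data[, , 7])
  expect_warning(glob <- sts_mip(v, axis = 3, slab_mm = 10), "global MIP")
  expect_equal(glob[, , 1], apply(v$data, c(1, 2), max))
})

test_that("a straight tube is tracked to its length and diameter", {
  grid <- recon_grid(c(60, 40, 40), 0.1)
  prim <- matrix(c(1, -1.5, 0, 0, 1.5, 0, 0, 0.25, hu_to_mu(600), 1),
                 nrow = 1)
  vol <- new_volume(array(mococt:::cpp_voxelize(prim, grid$n, grid$voxel,
                                                grid$origin), dim = grid$n),
                    grid$voxel, grid$origin)
  tk <- track_vessel(vol, c(-1.4, 0, 0), 300)
  expect_equal(tk$tracked_length, 3.0, tolerance = 0.05 * 3 + 0.2)
  expect_lt(abs(stats::median(tk$branches[[1]]$diameter) - 0.5), 0.11)
  expect_error(track_vessel(vol, c(0, 1.5, 0), 300), "below the threshold")
  empty <- vol; empty$data[] <- 0
  expect_error(track_vessel(empty, c(0, 0, 0), 300), "above threshold")
})

test_that("both branches of a bifurcation are discoverable from the trunk", {
  grid <- recon_grid(c(60, 40, 40), 0.1)
  prims <- rbind(
    c(1, -1.5, 0, 0, 1.5, 0, 0, 0.25, hu_to_mu(600), 1),
    c(1, 1.5, 0, 0, 2.6, 0.9, 0, 0.2, hu_to_mu(600), 1),
    c(1, 1.5, 0, 0, 2.6, -0.9, 0, 0.2, hu_to_mu(600), 1))
  vol <- new_volume(array(mococt:::cpp_voxelize(prims, grid$n, grid$voxel,
                                                grid$origin), dim = grid$n),
                    grid$voxel, grid$origin)
  tk <- track_vessel(vol, c(-1.4, 0, 0), 300, n_branches = 2)
  expect_equal(length(tk$branches), 2)
  ends <- t(sapply(tk$branches, function(b) b$points[nrow(b$points), ]))
  expect_equal(sort(ends[, 2]), c(-0.9, 0.9), tolerance = 0.15)
})

test_that("the temporal sampling bound follows from rate and phase count", {
  expect_equal(temporal_sampling_bound(300, 5), 40)
  expect_equal(temporal_sampling_bound(600, 10), 10)
  expect_error(temporal_sampling_bound(0, 5), "invalid")
})

test_that("dose sweep bookkeeping maps dose to frame fraction", {
  mo <- fx_moco()
  d <- fx_dyn()
  expect_error(dose_sweep(d$ps, d$track, mo$gspec, mo$grid,
                          dose_levels_mGy = 6000), "nominal")
  res <- suppressWarnings(
    dose_sweep(d$ps, d$track, mo$gspec, mo$grid, dose_levels_mGy = 1000,
               methods = "PC", seed = 2L, resp_bin = 3))
  expect_equal(res$frame_fraction, 0.2)        # 1000 of 5000 mGy
  res2 <- suppressWarnings(
    dose_sweep(d$ps, d$track, mo$gspec, mo$grid, dose_levels_mGy = 1000,
               methods = "PC", seed = 2L, resp_bin = 3))
  expect_identical(res$sigma_hu, res2$sigma_hu)   # bit-reproducible
  expect_identical(res$cnr, res2$cnr)
})

test_that("line sampling and LV radius agree with the analytic phantom", {
  spec <- phantom_spec(ejection_amplitude = 0, resp_amplitude_mm = 0,
                       resp_ap_frac = 0)
  st <- phantom_instantiate(spec, 0)
  grid <- recon_grid(96, 0.1)
  vol <- voxelize_phantom(st, grid)
  r <- lv_inner_radius(vol, st)
  true_r <- st$primitives[which(st$labels == "lv_blood"), 5]
  expect_equal(r, true_r, tolerance = 0.1)
})
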