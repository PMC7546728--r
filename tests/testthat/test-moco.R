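blob_volume <- function(center, n = 48, voxel = 0.1, sigma2 = 0.64) {
  org <- recon_grid(n, voxel)$origin
  ax <- org[1] + (seq_len(n) - 1) * voxel
  d2 <- outer(outer((ax - center[1])^2, (ax - center[2])^2, "+"),
              (ax - center[3])^2, "+")
  new_volume(exp(-d2 / (2 * sigma2)), voxel, org)
}

test_that("registering a volume to itself returns a negligible field", {
  f <- blob_volume(c(0, 0, 0))
  fld <- demons_register(f, f)
  expect_lt(mococt:::max_displacement_vox(fld), 0.05)
})

test_that("a known two-voxel translation is recovered in the blob interior", {
  f <- blob_volume(c(0, 0, 0))
  m <- blob_volume(c(0.2, 0, 0))
  fld <- demons_register(f, m)
  interior <- f$data > 0.3
  ux <- fld$u[, , , 1][interior] / f$voxel
  expect_lt(abs(mean(ux) - 2), 0.25)
  expect_lt(mean(abs(fld$u[, , , 2][interior])) / f$voxel, 0.25)
})

test_that("a contracting shell yields a compressive Jacobian", {
  n <- 48; voxel <- 0.1
  org <- recon_grid(n, voxel)$origin
  ax <- org[1] + (seq_len(n) - 1) * voxel
  shell <- function(s) {
    r <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
    new_volume(exp(-(r - 1.2 * s)^2 / (2 * 0.09)), voxel, org)
  }
  fld <- demons_register(shell(1), shell(0.95))
  J <- field_jacobian(fld)
  r <- sqrt(outer(outer(ax^2, ax^2, "+"), ax^2, "+"))
  ring <- abs(r - 1.14) < 0.15
  expect_lt(mean(J[ring]), 1)
})

test_that("non-overlapping intensity ranges trigger a warning", {
  a <- blob_volume(c(0, 0, 0))
  b <- a; b$data <- b$data + 10
  expect_warning(demons_register(a, b, levels = 1, iterations = 1),
                 "overlap")
})

test_that("already-cyclic fields pass through loop closure unchanged", {
  dims <- c(16, 16, 16)
  org <- recon_grid(16, 0.2)$origin
  zero <- lapply(1:6, function(i)
    motion_vector_field(array(0, dim = c(dims, 3)), 0.2, org))
  out <- enforce_cyclicity(zero)
  expect_equal(attr(out, "residual_after"), 0)
  for (i in 1:6) expect_equal(out[[i]]$u, zero[[i]]$u)
})

test_that("identical translations collapse to zero under loop closure", {
  dims <- c(16, 16, 16)
  org <- recon_grid(16, 0.2)$origin
  tfield <- function() {
    u <- array(0, dim = c(dims, 3)); u[, , , 1] <- 0.1   # 0.5 voxel each
    motion_vector_field(u, 0.2, org)
  }
  fields <- lapply(1:5, function(i) tfield())
  out <- enforce_cyclicity(fields)
  for (i in 1:5)
    expect_lt(mococt:::max_displacement_vox(out[[i]]), 0.02)
})

test_that("seeded random smooth fields close the loop after correction", {
  dims <- c(20, 20, 20)
  org <- recon_grid(20, 0.2)$origin
  set.seed(33)
  mk <- function() {
    u <- array(stats::rnorm(prod(dims) * 3, 0, 0.08), dim = c(dims, 3))
    for (c2 in 1:3)
      u[, , , c2] <- array(mococt:::cpp_gauss_smooth(
        as.numeric(u[, , , c2]), dims, 2.5), dim = dims)
    u <- u * (0.2 / max(abs(u)))     # about one voxel peak displacement
    motion_vector_field(u, 0.2, org)
  }
  fields <- lapply(1:8, function(i) mk())
  out <- enforce_cyclicity(fields)
  expect_lt(attr(out, "residual_after"), 0.1)
  expect_gt(attr(out, "residual_before") / attr(out, "residual_after"), 10)
})

test_that("field composition and inversion behave consistently", {
  f <- blob_volume(c(0, 0, 0))
  m <- blob_volume(c(0.2, 0.1, 0))
  fld <- demons_register(f, m)
  inv <- invert_field(fld)
  comp <- compose_fields(fld, inv)
  interior <- f$data > 0.3
  mag <- sqrt(apply(comp$u^2, 1:3, sum)) / f$voxel
  expect_lt(mean(mag[interior]), 0.1)
})

test_that("warping preserves the mass of a compact structure", {
  f <- blob_volume(c(0, 0, 0))
  m <- blob_volume(c(0.2, 0, 0))
  fld <- demons_register(f, m)
  w <- warp_volume(m, fld)
  expect_lt(abs(sum(w$data) / sum(f$data) - 1), 0.02)
})

test_that("static phantom with identity fields averages the phase volumes", {
  ms <- fx_moco_static()
  series <- suppressWarnings(
    reconstruct_phase_series(ms$ps, ms$track, ms$gspec, ms$grid,
                             resp_bin = 1))
  dims <- ms$grid$n
  ident <- lapply(1:10, function(i)
    motion_vector_field(array(0, dim = c(dims, 3)), ms$grid$voxel,
                        ms$grid$origin))
  out <- motion_compensate(series, ident, 1)
  manual <- Reduce(`+`, lapply(series$volumes, function(v) v$data)) / 10
  expect_equal(out$data, manual, tolerance = 1e-12)
  expect_error(motion_compensate(series, ident[1:3], 1), "one field")
})

test_that("motion compensation restores noise to the standard level", {
  ms <- fx_moco_static()
  s_std <- noise_sd_pair(ms$a$std, ms$b$std, ms$roi)
  s_pc <- noise_sd_pair(ms$a$pc, ms$b$pc, ms$roi)
  s_moco <- noise_sd_pair(ms$a$moco, ms$b$moco, ms$roi)
  # N = 10 cardiac bins partition a 100% respiratory window, so the MoCo
  # photon budget equals the standard reconstruction's
  expect_lt(abs(s_moco - s_std) / s_std, 0.2)
  expect_equal(s_moco / s_pc, 1 / sqrt(10), tolerance = 0.15)
})

test_that("MoCo keeps the reference-phase LV radius of the PC volume", {
  mo <- fx_moco()
  r_pc <- lv_inner_radius(mo$series$volumes[[1]], mo$state)
  r_moco <- lv_inner_radius(mo$moco, mo$state)
  expect_lt(abs(r_pc - r_moco), mo$grid$voxel)
})

test_that("MoCo does not blur the coronary cross-section", {
  mo <- fx_moco()
  pt <- mo$state$centerline$trunk$points
  i <- 3
  tangent <- pt[i + 1, ] - pt[i - 1, ]
  perp <- c(-tangent[2], tangent[1], 0)
  step <- mo$grid$voxel / 4
  w_ref <- profile_fwhm(mo$pc_noiseless, pt[i, ], perp, 1.0, step)
  w_moco <- profile_fwhm(mo$moco, pt[i, ], perp, 1.0, step)
  expect_lt(abs(w_moco - w_ref) / w_ref, 0.2)
})

test_that("displacement fields export as multi-component NIfTI", {
  dims <- c(8, 8, 8)
  u <- array(stats::rnorm(prod(dims) * 3, 0, 0.1), dim = c(dims, 3))
  f <- motion_vector_field(u, 0.2, c(0, 0, 0))
  path <- tempfile(fileext = ".nii.gz")
  write_field(f, path)
  img <- RNifti::readNifti(path)
  expect_equal(dim(img), c(dims, 3))
})
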