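test_that("cardiac phase is the fractional part of elapsed cycles", {
  expect_equal(cardiac_phase(0, 600), 0)
  expect_equal(cardiac_phase(0.1, 600), 0)     # exactly one 100 ms cycle
  expect_equal(cardiac_phase(0.025, 600), 0.25)
  expect_equal(respiratory_phase(0.05, 300), 0.25)
  expect_error(cardiac_phase(1, 0), "positive")
  expect_error(respiratory_phase(1, -10), "positive")
})

test_that("spec validation rejects non-physical parameters", {
  expect_error(phantom_spec(heart_rate = 0), "rates")
  expect_error(phantom_spec(heart_long_axis = 3, heart_short_axis = 4),
               "long axis")
  expect_error(phantom_spec(coronary_mean_diameter_um = 500), "mean coronary")
  expect_error(phantom_spec(ejection_amplitude = 1.2), "ejection")
})

test_that("motionless spec gives a time-invariant state", {
  spec <- phantom_spec(ejection_amplitude = 0, resp_amplitude_mm = 0,
                       resp_ap_frac = 0)
  s1 <- phantom_instantiate(spec, 0)
  s2 <- phantom_instantiate(spec, 0.123)
  expect_equal(s1$primitives, s2$primitives)
})

test_that("attenuation is exactly periodic in the cardiac cycle", {
  spec <- phantom_spec(heart_rate = 587, resp_amplitude_mm = 0,
                       resp_ap_frac = 0)
  period <- 60 / 587
  set.seed(1)
  pts <- matrix(stats::runif(90, -2.5, 2.5), ncol = 3)
  m1 <- attenuation_at(phantom_instantiate(spec, 0.123), pts)
  m2 <- attenuation_at(phantom_instantiate(spec, 0.123 + 3 * period), pts)
  expect_equal(m1, m2)
})

test_that("myocardial shell volume is conserved over the cycle", {
  spec <- phantom_spec(heart_rate = 587, resp_amplitude_mm = 0,
                       resp_ap_frac = 0)
  period <- 60 / 587
  # dense-grid integration oracle at end-diastole and peak systole
  v_ed <- myocardial_volume(phantom_instantiate(spec, 0), voxel = 0.06)
  v_es <- myocardial_volume(phantom_instantiate(spec, 0.175 * period),
                            voxel = 0.06)
  expect_lt(abs(v_es - v_ed) / v_ed, 0.02)
})

test_that("coronary diameters taper monotonically from a rigid 400 um ostium", {
  spec <- desk_phantom_spec()
  s0 <- phantom_instantiate(spec, 0)
  s1 <- phantom_instantiate(spec, 0.03)
  # ostium diameter is a rigid property of the vessel, not deformed
  expect_equal(s0$centerline$trunk$diameter[1], 0.4)
  expect_equal(s1$centerline$trunk$diameter[1], 0.4)
  main <- c(s0$centerline$trunk$diameter, s0$centerline$oma$diameter)
  expect_true(all(diff(main) <= 1e-12))
  expect_equal(max(main), 0.4)
  expect_equal(min(main), 0.5 * 0.160, tolerance = 0.02)
})

test_that("compound-primitive evaluation follows the priority rule", {
  spec <- phantom_spec()
  st <- phantom_instantiate(spec, 0)
  lv <- which(st$labels == "lv_blood")
  ctr <- st$primitives[lv, 2:4]
  mu_bl <- hu_to_mu(spec$blood_enhancement_hu)
  mu_bg <- hu_to_mu(spec$background_hu)
  # LV centre lies inside both the myocardial ellipsoid and the cavity:
  # the higher-priority blood pool wins
  expect_equal(attenuation_at(st, matrix(ctr, 1)), mu_bl)
  # inside the thorax but outside all anatomy -> background
  expect_equal(attenuation_at(st, matrix(c(4.0, 0, -3), 1)), mu_bg)
  # far outside everything -> air
  expect_equal(attenuation_at(st, matrix(c(50, 50, 50), 1)), 0)
  expect_error(attenuation_at(st, matrix(c(NA, 0, 0), 1)), "finite")
})

test_that("HU conversion round trip is exact", {
  mu <- c(0.015, 0.02, 0.032)
  expect_equal(hu_to_mu(mu_to_hu(mu)), mu)
  expect_equal(mu_to_hu(0.02), 0)
})

test_that("phantom spec YAML round trip preserves all fields", {
  spec <- desk_phantom_spec(blood_enhancement_hu = 550)
  path <- tempfile(fileext = ".yaml")
  write_phantom_spec(spec, path)
  spec2 <- read_phantom_spec(path)
  expect_equal(unclass(spec2), unclass(spec))
})

test_that("voxelization exports and reloads through NIfTI", {
  spec <- phantom_spec()
  grid <- recon_grid(24, 0.4)
  vol <- voxelize_phantom(phantom_instantiate(spec, 0), grid)
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$data, vol$data, tolerance = 1e-6)
  expect_equal(back$voxel, vol$voxel)
  expect_equal(back$origin, vol$origin)
})
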