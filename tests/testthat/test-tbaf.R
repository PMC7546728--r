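noisy_cube <- function(seed, n = 48, sd = 0.002, base = 0.02) {
  set.seed(seed)
  new_volume(array(base + stats::rnorm(n^3, 0, sd), dim = rep(n, 3)),
             0.1, recon_grid(n, 0.1)$origin)
}

test_that("structure tensor vanishes on a constant volume", {
  v <- new_volume(array(1, dim = c(24, 24, 24)), 0.1,
                  recon_grid(24, 0.1)$origin)
  tf <- structure_tensor(v)
  expect_equal(max(abs(tf$l1)), 0)
  expect_error(structure_tensor(v, sigma_g = 0), "scales")
})

test_that("eigenvectors align with edge normals and tube axes", {
  n <- 40
  org <- recon_grid(n, 0.1)$origin
  edge <- array(rep(as.numeric(seq_len(n) > 20), times = n * n),
                dim = c(n, n, n))
  tf <- structure_tensor(new_volume(edge * 0.01 + 0.02, 0.1, org))
  expect_gt(abs(tf$e1[21, 20, 20, 1]), 0.99)   # major axis = edge normal x
  tube <- array(0, dim = c(n, n, n))
  tube[19:21, 19:21, ] <- 0.01
  tft <- structure_tensor(new_volume(tube + 0.02, 0.1, org))
  expect_gt(abs(tft$e3[20, 20, 20, 3]), 0.95)  # minor axis = tube axis z
})

test_that("a constant volume passes through the filter unchanged", {
  v <- new_volume(array(0.02, dim = c(24, 24, 24)), 0.1,
                  recon_grid(24, 0.1)$origin)
  out <- tbaf_filter(v)
  expect_equal(out$data, v$data)
})

test_that("uniform noise is reduced with the mean preserved", {
  v <- noisy_cube(10)
  out <- tbaf_filter(v)
  core <- 6:43
  s0 <- stats::sd(v$data[core, core, core])
  s1 <- stats::sd(out$data[core, core, core])
  expect_lt(s1 / s0, 0.7)                                  # >= 30% reduction
  expect_lt(abs(mean(out$data) - mean(v$data)) / mean(v$data), 0.001)
  # adaptivity: a second application removes strictly less noise
  out2 <- tbaf_filter(out)
  s2 <- stats::sd(out2$data[core, core, core])
  expect_lt(1 - s2 / s1, 1 - s1 / s0)
})

test_that("edges keep their width while flat regions are denoised", {
  n <- 48; core <- 8:41
  set.seed(12)
  org <- recon_grid(n, 0.1)$origin
  step <- array(0.02, dim = rep(n, 3)); step[, 1:24, ] <- 0.03
  v <- new_volume(step + array(stats::rnorm(n^3, 0, 0.002), dim = rep(n, 3)),
                  0.1, org)
  out <- tbaf_filter(v)
  esf_width <- function(a) {
    p <- apply(a[core, , core], 2, mean)
    pm <- cummin(p)                     # monotonize the mean profile
    x10 <- stats::approx(rev(pm), rev(seq_len(n)), xout = 0.029,
                         ties = "ordered")$y
    x90 <- stats::approx(rev(pm), rev(seq_len(n)), xout = 0.021,
                         ties = "ordered")$y
    abs(x90 - x10)
  }
  w0 <- esf_width(v$data)
  w1 <- esf_width(out$data)
  expect_lt((w1 - w0) / w0, 0.15)
  flat <- 32:43
  s0 <- stats::sd(v$data[core, flat, core])
  s1 <- stats::sd(out$data[core, flat, core])
  expect_lt(s1 / s0, 0.7)
})

test_that("no staircasing on a noisy ramp relative to a bilateral baseline", {
  n <- 48; core <- 8:41
  org <- recon_grid(n, 0.1)$origin
  ramp <- array(0, dim = rep(n, 3))
  for (k in seq_len(n))
    ramp[, , k] <- matrix(rep(seq(0, 0.0008 * (n - 1), length.out = n),
                              times = n), n, n)
  set.seed(3)
  v <- new_volume(0.02 + ramp + array(stats::rnorm(n^3, 0, 0.0015),
                                      dim = rep(n, 3)), 0.1, org)
  flat <- new_volume(array(0.02 + stats::rnorm(n^3, 0, 0.0015),
                           dim = rep(n, 3)), 0.1, org)
  red <- function(out) 1 - stats::sd(out$data[core, core, core]) /
    stats::sd(flat$data[core, core, core])
  target <- red(tbaf_filter(flat))
  srs <- seq(0.0010, 0.0022, by = 0.0002)
  reds <- vapply(srs, function(sr) red(bilateral_filter(flat, 1.5, sr)),
                 numeric(1))
  sr_matched <- stats::approx(reds, srs, xout = target)$y
  dev_from_plane <- function(a) {
    df <- data.frame(y = as.numeric(a), x = as.numeric(slice.index(a, 1)))
    stats::mad(stats::residuals(stats::lm(y ~ x, data = df)))
  }
  d_tbaf <- dev_from_plane(tbaf_filter(v)$data[core, core, core])
  d_bil <- dev_from_plane(
    bilateral_filter(v, 1.5, sr_matched)$data[core, core, core])
  expect_lt(d_tbaf, d_bil)
})

test_that("the local noise estimator recovers a known sigma", {
  v <- noisy_cube(21, sd = 0.003)
  sn <- local_noise_sd(v)
  expect_equal(stats::median(sn), 0.003, tolerance = 0.1)
})
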