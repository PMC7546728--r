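test_that("gating windows validate and centre correctly", {
  gs <- gating_spec()
  expect_equal(gs$resp_centers, c(0.125, 0.375, 0.625, 0.875))
  expect_equal(gs$cardiac_centers[1], 0.05)
  expect_error(gating_spec(resp_width = 0), "widths")
  expect_error(gating_spec(cardiac_width = 1.2), "widths")
})

test_that("windows are half-open and wrap around phase zero", {
  w <- mococt:::in_window
  expect_true(w(0.05, 0.1, 0.1))       # left edge included
  expect_false(w(0.15, 0.1, 0.1))      # right edge excluded
  # a window centred at 0 picks up phases on both sides of the wrap
  expect_true(w(0.99, 0, 0.1))
  expect_true(w(0.01, 0, 0.1))
  expect_false(w(0.06, 0, 0.1))
})

test_that("bin labels equal an exhaustive brute-force interval check", {
  gs <- gating_spec()
  set.seed(42)
  n <- 100
  track <- phase_track(seq_len(n) / 86, stats::runif(n), stats::runif(n))
  bins <- suppressWarnings(assign_bins(track, gs))
  for (i in seq_len(n)) {
    cb <- NA_integer_; rb <- NA_integer_
    for (k in seq_len(10)) {
      d <- ((track$cardiac[i] - gs$cardiac_centers[k] + 0.5) %% 1) - 0.5
      if (d >= -0.05 && d < 0.05) cb <- k
    }
    for (k in seq_len(4)) {
      d <- ((track$respiratory[i] - gs$resp_centers[k] + 0.5) %% 1) - 0.5
      if (d >= -0.125 && d < 0.125) rb <- k
    }
    expect_identical(bins$cardiac_bin[i], cb)
    expect_identical(bins$resp_bin[i], rb)
  }
})

test_that("non-overlapping full-cover windows partition every frame", {
  gs <- gating_spec()   # widths equal spacing: a partition of [0,1)
  set.seed(7)
  n <- 4000
  track <- phase_track(seq_len(n) / 86, stats::runif(n), stats::runif(n))
  bins <- suppressWarnings(assign_bins(track, gs))
  expect_false(anyNA(bins$cardiac_bin))
  expect_false(anyNA(bins$resp_bin))
  joint_total <- sum(bins$joint_mask)
  expect_equal(joint_total, n)          # each frame in exactly one joint bin
  full <- gating_spec(n_resp_bins = 1, resp_width = 1,
                      n_cardiac_bins = 1, cardiac_width = 1)
  b2 <- assign_bins(track, full)
  expect_true(all(b2$joint_mask))
})

test_that("empty joint bins trigger a warning naming the bin", {
  gs <- gating_spec(n_resp_bins = 2, resp_width = 0.5,
                    n_cardiac_bins = 2, cardiac_width = 0.5)
  track <- phase_track(1:50 / 86, rep(0.3, 50), rep(0.3, 50))
  w <- capture_warnings(assign_bins(track, gs))
  expect_true(any(grepl("empty joint bin", w)))
})

test_that("phase tracks are validated and reproducible", {
  expect_error(phase_track(1:3, c(0.1, 1.0, 0.2), c(0, 0, 0)), "phases")
  d <- fx_dyn()
  t2 <- extract_gating_signals(d$psn)
  expect_identical(t2$cardiac, d$track$cardiac)
  expect_identical(t2$respiratory, d$track$respiratory)
})

test_that("intrinsic gating recovers desk-scenario rates and phases", {
  d <- fx_dyn()
  tr <- d$track
  expect_lt(abs(tr$cardiac_rate_bpm / d$spec$heart_rate - 1), 0.01)
  expect_lt(abs(tr$resp_rate_rpm / d$spec$resp_rate - 1), 0.01)
  expect_lt(circular_phase_rms(tr$cardiac, d$ps$true_phases$cardiac), 0.05)
  expect_lt(circular_phase_rms(tr$respiratory, d$ps$true_phases$respiratory),
            0.05)
})

test_that("a motionless scan raises a gating failure naming the band", {
  spec <- desk_phantom_spec(ejection_amplitude = 0, resp_amplitude_mm = 0,
                            resp_ap_frac = 0)
  g <- desk_geometry(n_cols = 32, n_rows = 24, scan_duration = 10,
                     photons_per_frame = 1e5)
  ps <- apply_noise(simulate_scan(spec, g), 1, seed = 9L)
  expect_error(extract_gating_signals(ps), "respiratory")
})

test_that("phase track CSV export includes bins", {
  d <- fx_dyn()
  bins <- suppressWarnings(assign_bins(d$track, gating_spec()))
  path <- tempfile(fileext = ".csv")
  write_phase_track(d$track, path, bins)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), d$track$n_frames)
  expect_true(all(c("cardiac", "respiratory", "cardiac_bin") %in% names(df)))
})

test_that("circular RMS handles wrap-around and constant offsets", {
  ph <- stats::runif(500)
  expect_equal(circular_phase_rms(ph, ph), 0)
  expect_lt(circular_phase_rms((ph + 0.4) %% 1, ph, align = TRUE), 1e-10)
  expect_equal(circular_phase_rms((ph + 0.4) %% 1, ph, align = FALSE), 0.4,
               tolerance = 1e-6)
})
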