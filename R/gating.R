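#' Gating window specification
#'
#' Non-overlapping cardiac and respiratory gating windows. Defaults follow
#' the acquisition protocol this package emulates: four respiratory windows
#' of width 25\% and ten cardiac windows of width 10\%, centres equispaced
#' at (k + 0.5)/n.
#'
#' @param n_resp_bins,n_cardiac_bins number of windows.
#' @param resp_width,cardiac_width window widths as fractions of the cycle.
#' @export
gating_spec <- function(n_resp_bins = 4, resp_width = 0.25,
                        n_cardiac_bins = 10, cardiac_width = 0.10) {
  if (resp_width <= 0 || resp_width > 1 || cardiac_width <= 0 ||
      cardiac_width > 1)
    stop("window widths must be in (0, 1]")
  structure(list(n_resp_bins = as.integer(n_resp_bins),
                 resp_width = resp_width,
                 n_cardiac_bins = as.integer(n_cardiac_bins),
                 cardiac_width = cardiac_width,
                 resp_centers = (seq_len(n_resp_bins) - 0.5) / n_resp_bins,
                 cardiac_centers = (seq_len(n_cardiac_bins) - 0.5) /
                   n_cardiac_bins),
            class = "gating_spec")
}

# circular membership in a half-open window [center - w/2, center + w/2)
in_window <- function(phase, center, width) {
  d <- ((phase - center + 0.5) %% 1) - 0.5
  d >= -width / 2 & d < width / 2
}

# dominant spectral frequency of x (sampled at fs) within band [f0, f1] Hz
dominant_frequency <- function(x, fs, band, label) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))[seq_len(floor(n / 2))]
  fr <- (seq_len(floor(n / 2)) - 1) * fs / n
  sel <- fr >= band[1] & fr <= band[2]
  if (!any(sel)) stop("gating failure: empty search band for ", label)
  pk <- max(sp[sel])
  floor_level <- stats::median(sp[sel])
  if (!is.finite(pk) || pk < 4 * floor_level)
    stop("gating failure: no spectral peak above noise floor in the ",
         label, " band")
  fr[sel][which.max(sp[sel])]
}

# zero-phase band-pass around f0 (Butterworth order 4 applied forward and
# backward)
bandpass_around <- function(x, fs, f0, rel_width = 0.4) {
  lo <- max(f0 * (1 - rel_width), 1e-3)
  hi <- min(f0 * (1 + rel_width), 0.49 * fs)
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# subtract the gantry-angle-locked component (mean signal per 5 degree
# sector over all revolutions); removes rotation harmonics from surrogates
remove_angle_locked <- function(x, angles, n_rev) {
  if (n_rev < 2) return(x - mean(x))
  sector <- floor(angles / (2 * pi) * 72) + 1
  x - stats::ave(x, sector)
}

# surrogate peak times at sub-sample precision: integer maxima (minimum
# spacing 0.6 cycles) refined by a parabolic fit through the three samples
# around each peak
find_peak_times <- function(x, fs, f0, time) {
  p <- pracma::findpeaks(x, minpeakdistance = max(2, floor(0.6 * fs / f0)))
  if (is.null(p) || nrow(p) < 3)
    stop("gating failure: too few surrogate peaks")
  idx <- sort(p[, 2])
  idx <- idx[idx > 1 & idx < length(x)]
  frac <- vapply(idx, function(i) {
    denom <- x[i - 1] - 2 * x[i] + x[i + 1]
    if (abs(denom) < 1e-12) 0 else 0.5 * (x[i - 1] - x[i + 1]) / denom
  }, numeric(1))
  time[idx] + pmax(-0.5, pmin(0.5, frac)) / fs
}

# peak-to-peak linear phase ramp; constant-period extrapolation at the ends
peaks_to_phase <- function(time, tp) {
  if (length(tp) < 3) stop("gating failure: fewer than 3 surrogate peaks")
  period <- mean(diff(tp))
  knots <- c(tp[1] - period * 100, tp, tp[length(tp)] + period * 100)
  cyc <- c(-100, seq_along(tp) - 1, length(tp) - 1 + 100)
  stats::approx(knots, cyc, xout = time, rule = 2)$y %% 1
}

#' Intrinsic gating: derive phases from the projection data
#'
#' Constructs cardiac and respiratory surrogate signals from the raw
#' projections themselves (no ECG leads or breathing sensor): the
#' respiratory surrogate is the row-wise (craniocaudal) centre of mass of
#' the detector intensity per frame, cleaned of the gantry-angle-locked
#' component, band-pass filtered (zero-phase Butterworth, order 4) around
#' the dominant spectral peak in the respiratory search band, and converted
#' to phase by a linear 0 to 1 ramp between consecutive surrogate peaks
#' (phase 0 = the surrogate peak, i.e. end-inspiration). The cardiac
#' surrogate is the total intensity over the central detector rows - the
#' projected attenuation mass, which is invariant under gantry rotation and
#' modulated coherently at every angle by the cardiac blood volume - cleaned
#' of the angle-locked and respiration-phase-locked components, band-pass
#' filtered around the dominant cardiac spectral peak and converted to phase
#' by the same peak-to-peak ramp (phase 0 = the cardiac surrogate peak, a
#' constant physiological offset from any particular cardiac event).
#'
#' @param ps a \code{projection_set} (at least ~10 s of frames so the
#'   spectral peaks are resolvable).
#' @param resp_band,cardiac_band spectral search bands, Hz.
#' @return a \code{phase_track}: per-frame phases, estimated rates and the
#'   raw/filtered surrogates for audit.
#' @export
extract_gating_signals <- function(ps, resp_band = c(1, 8),
                                   cardiac_band = c(6, 15)) {
  d <- dim(ps$frames)
  nr <- d[1]; nc <- d[2]; nf <- d[3]
  fs <- ps$geometry$framerate
  if (nf / fs < 5) stop("need several seconds of frames for gating")
  tl <- ps$timeline

  # respiratory surrogate: row-wise centre of mass per frame
  rows_mat <- apply(ps$frames, c(1, 3), sum)      # nr x nf
  wsum <- colSums(rows_mat)
  wsum[wsum <= 0] <- 1
  resp_raw <- colSums(rows_mat * seq_len(nr)) / wsum
  resp_cl <- remove_angle_locked(resp_raw, tl$angle, tl$n_revolutions)
  f_resp <- dominant_frequency(resp_cl, fs, resp_band, "respiratory")
  resp_f <- bandpass_around(resp_cl, fs, f_resp)

  # provisional respiratory phase, used to strip respiration-locked content
  # (all its harmonics) from the cardiac residuals
  rp0 <- find_peak_times(resp_f, fs, f_resp, tl$time)
  resp_phase0 <- peaks_to_phase(tl$time, rp0)

  # cardiac surrogate: total intensity over the central detector rows.
  # The summed line integral measures the projected attenuation mass, which
  # is invariant under gantry rotation, so the cardiac blood-volume
  # modulation (ventricles emptying into the systemic circulation) adds
  # coherently at every angle; region-mean surrogates decohere because the
  # modulation sign varies across the detector. The central-row restriction
  # keeps the craniocaudally translating body edge outside the sum.
  fm <- matrix(ps$frames, nr * nc, nf)
  roi <- matrix(FALSE, nr, nc)
  roi[seq.int(ceiling(nr * 0.2), floor(nr * 0.8)), ] <- TRUE
  card_raw <- colMeans(fm[roi, , drop = FALSE])
  card_cl <- remove_angle_locked(card_raw, tl$angle, tl$n_revolutions)
  # additionally strip the respiration-phase-locked component (all
  # respiratory harmonics). When heart and respiratory rates are
  # commensurate the cardiac signal itself is respiration-locked and the
  # stripping removes it together with the harmonics; in that case fall
  # back to the unstripped surrogate (band separation then governs).
  card_rs <- card_cl - stats::ave(card_cl, floor(resp_phase0 * 24))
  band_peak <- function(x) {
    sp <- Mod(stats::fft(x - mean(x)))[seq_len(floor(nf / 2))]
    fr <- (seq_len(floor(nf / 2)) - 1) * fs / nf
    max(sp[fr >= cardiac_band[1] & fr <= cardiac_band[2]])
  }
  if (band_peak(card_rs) >= 0.3 * band_peak(card_cl)) card_cl <- card_rs
  f_card <- dominant_frequency(card_cl, fs, cardiac_band, "cardiac")
  card_f <- bandpass_around(card_cl, fs, f_card)
  cp <- find_peak_times(card_f, fs, f_card, tl$time)
  card_phase <- peaks_to_phase(tl$time, cp)
  card_rate <- 60 * (length(cp) - 1) / (cp[length(cp)] - cp[1])

  rp <- find_peak_times(resp_f, fs, f_resp, tl$time)
  resp_rate <- 60 * (length(rp) - 1) / (rp[length(rp)] - rp[1])

  structure(list(frame = tl$index, time = tl$time,
                 cardiac = card_phase,
                 respiratory = peaks_to_phase(tl$time, rp),
                 cardiac_rate_bpm = card_rate,
                 resp_rate_rpm = resp_rate,
                 surrogates = list(resp_raw = resp_raw, resp_filtered = resp_f,
                                   cardiac_raw = card_raw,
                                   cardiac_filtered = card_f,
                                   cardiac_roi = matrix(roi, nr, nc)),
                 n_frames = nf),
            class = "phase_track")
}

#' Build a phase track from known phases
#'
#' Wraps externally known (e.g. simulator ground-truth) phases in the
#' container used by the binning and reconstruction steps.
#'
#' @param time,cardiac,respiratory per-frame values; phases in [0,1).
#' @export
phase_track <- function(time, cardiac, respiratory) {
  stopifnot(length(cardiac) == length(time),
            length(respiratory) == length(time))
  if (any(cardiac < 0 | cardiac >= 1 | respiratory < 0 | respiratory >= 1))
    stop("phases must lie in [0, 1)")
  structure(list(frame = seq_along(time), time = time, cardiac = cardiac,
                 respiratory = respiratory,
                 cardiac_rate_bpm = NA_real_, resp_rate_rpm = NA_real_,
                 surrogates = NULL, n_frames = length(time)),
            class = "phase_track")
}

#' @export
print.phase_track <- function(x, ...) {
  cat(sprintf("<phase_track> %d frames, cardiac %.1f bpm, respiratory %.1f rpm\n",
              x$n_frames, x$cardiac_rate_bpm, x$resp_rate_rpm))
  invisible(x)
}

#' Assign frames to gating bins
#'
#' A frame belongs to joint bin (c, r) iff its cardiac phase falls in
#' cardiac window c and its respiratory phase in respiratory window r
#' (half-open windows, circular wrap-around at 1). With uniform phases the
#' expected fraction per joint bin is cardiac_width * resp_width (2.5\% at
#' the default 10\% x 25\% windows).
#'
#' @param track a \code{phase_track}; @param spec a \code{gating_spec}.
#' @return list with per-frame labels (\code{cardiac_bin}, \code{resp_bin},
#'   NA when no window contains the phase), logical selection masks per
#'   cardiac window, respiratory window and joint bin, and bookkeeping.
#' @export
assign_bins <- function(track, spec) {
  nc <- spec$n_cardiac_bins; nr <- spec$n_resp_bins
  cbin <- rep(NA_integer_, track$n_frames)
  rbin <- rep(NA_integer_, track$n_frames)
  cmask <- matrix(FALSE, track$n_frames, nc)
  rmask <- matrix(FALSE, track$n_frames, nr)
  for (k in seq_len(nc)) {
    m <- in_window(track$cardiac, spec$cardiac_centers[k], spec$cardiac_width)
    cmask[, k] <- m
    cbin[m] <- k
  }
  for (k in seq_len(nr)) {
    m <- in_window(track$respiratory, spec$resp_centers[k], spec$resp_width)
    rmask[, k] <- m
    rbin[m] <- k
  }
  joint <- array(FALSE, dim = c(track$n_frames, nc, nr))
  for (r in seq_len(nr))
    for (c in seq_len(nc)) {
      joint[, c, r] <- cmask[, c] & rmask[, r]
      if (!any(joint[, c, r]))
        warning(sprintf("empty joint bin: cardiac %d, respiratory %d", c, r))
    }
  list(cardiac_bin = cbin, resp_bin = rbin, cardiac_mask = cmask,
       resp_mask = rmask, joint_mask = joint, spec = spec)
}

#' Circular RMS phase error
#'
#' Root-mean-square circular distance between two phase sequences in cycles;
#' optionally removes the best constant circular offset first (the intrinsic
#' surrogate fixes the phase origin only up to a physiological constant).
#'
#' @param est,truth phases in [0,1); @param align remove constant offset.
#' @export
circular_phase_rms <- function(est, truth, align = TRUE) {
  d <- (est - truth) %% 1
  if (align) {
    off <- Arg(mean(exp(2i * pi * d))) / (2 * pi)
    d <- d - off
  }
  d <- (d + 0.5) %% 1 - 0.5
  sqrt(mean(d^2))
}

#' Export a phase track as CSV for audit
#' @param track a \code{phase_track}; @param bins optional \code{assign_bins}
#'   result; @param path output file.
#' @export
write_phase_track <- function(track, path, bins = NULL) {
  df <- data.frame(frame = track$frame, time = track$time,
                   cardiac = track$cardiac, respiratory = track$respiratory)
  if (!is.null(bins)) {
    df$cardiac_bin <- bins$cardiac_bin
    df$resp_bin <- bins$resp_bin
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
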