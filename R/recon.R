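#' @useDynLib mococt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Discrete band-limited ramp kernel (sampled at detector pitch du at the
# isocenter), returned as its DFT over n_pad samples together with the
# apodization window. cutoff scales the Nyquist band edge (used to match
# the filter bandwidth to a coarser reconstruction grid).
ramp_transfer <- function(n_pad, du, apodization = c("shepp-logan", "ramlak"),
                          cutoff = 1) {
  apodization <- match.arg(apodization)
  h <- numeric(n_pad)
  h[1] <- 1 / (4 * du^2)
  k <- seq(1, n_pad / 2, by = 2)          # odd offsets
  h[1 + k] <- -1 / (pi^2 * k^2 * du^2)
  h[n_pad + 1 - k] <- -1 / (pi^2 * k^2 * du^2)
  H <- Re(stats::fft(h))
  freq <- c(seq(0, n_pad / 2), seq(-n_pad / 2 + 1, -1)) / (n_pad * du)
  nyq <- cutoff / (2 * du)
  w <- as.numeric(abs(freq) <= nyq)
  if (apodization == "shepp-logan") {
    x <- pi * abs(freq) / (2 * nyq)
    sl <- ifelse(x < 1e-9, 1, sin(pmin(x, pi)) / pmax(x, 1e-9))
    w <- w * sl
  }
  H * w
}

# cosine pre-weighting + row-wise ramp filtering of all frames; detector
# coordinates are rescaled to the isocenter plane before filtering.
filter_projections <- function(frames, geometry, apodization = "shepp-logan",
                               cutoff = 1) {
  d <- dim(frames)
  nr <- d[1]; nc <- d[2]; nf <- d[3]
  du <- geometry$detector_pixel_mm * geometry$R_F / geometry$R_FD
  u <- (seq_len(nc) - (nc + 1) / 2) * du
  v <- (seq_len(nr) - (nr + 1) / 2) * du
  cosw <- geometry$R_F / sqrt(geometry$R_F^2 +
                                outer(v^2, u^2, "+"))
  n_pad <- 2^ceiling(log2(2 * nc))
  H <- ramp_transfer(n_pad, du, apodization, cutoff)
  out <- array(0, dim = d)
  P <- matrix(0, n_pad, nr)
  for (f in seq_len(nf)) {
    P[] <- 0
    P[seq_len(nc), ] <- t(frames[, , f] * cosw)
    Fq <- stats::mvfft(P) * H
    filt <- Re(stats::mvfft(Fq, inverse = TRUE)) / n_pad
    out[, , f] <- t(filt[seq_len(nc), , drop = FALSE]) * du
  }
  list(filtered = out, du = du)
}

# Per-frame angular weights: 1/(local angular frame density) binned in
# sector_deg sectors, empty sectors redistributing their arc to the nearest
# occupied sector; the factor 1/2 accounts for full-scan redundancy.
angular_weights <- function(angles, sector_deg = 1, warn_empty = TRUE) {
  ns <- round(360 / sector_deg)
  sec <- floor((angles %% (2 * pi)) / (2 * pi) * ns) + 1
  counts <- tabulate(sec, nbins = ns)
  arc <- rep(2 * pi / ns, ns)
  empty <- which(counts == 0)
  occ <- which(counts > 0)
  if (length(occ) == 0) stop("no frames to weight")
  if (length(empty) > 0) {
    if (warn_empty)
      warning(length(empty), " angular sectors contain no frames; ",
              "their arc was assigned to the nearest occupied sector")
    for (s in empty) {
      d <- pmin(abs(occ - s), ns - abs(occ - s))
      nearest <- occ[which.min(d)]
      arc[nearest] <- arc[nearest] + arc[s]
      arc[s] <- 0
    }
  }
  arc[sec] / counts[sec] / 2
}

# occupied angular arc (rad) in sector resolution; 5 degree sectors so a
# sparse-but-even multi-revolution schedule counts as covered
angular_coverage <- function(angles, sector_deg = 5) {
  ns <- round(360 / sector_deg)
  sec <- unique(floor((angles %% (2 * pi)) / (2 * pi) * ns) + 1)
  length(sec) * 2 * pi / ns
}

#' FDK filtered-backprojection reconstruction
#'
#' Standard circular cone-beam reconstruction: cosine pre-weighting,
#' row-wise ramp filtering (Shepp-Logan apodization by default, cutoff at
#' the detector Nyquist frequency scaled by \code{cutoff}), and
#' distance-weighted backprojection with bilinear detector interpolation.
#' Multi-revolution scans are normalized by the local angular frame density
#' (1 degree sectors), so reconstructions from non-uniformly distributed
#' frame subsets remain quantitative.
#'
#' @param ps a \code{projection_set}.
#' @param grid a \code{recon_grid}.
#' @param apodization \code{"shepp-logan"} or \code{"ramlak"}.
#' @param cutoff ramp cutoff as a fraction of the detector Nyquist.
#' @param provenance optional provenance tag override.
#' @return a \code{ct_volume} (attenuation, 1/mm) with the out-of-field
#'   coverage fraction attached as \code{coverage}.
#' @export
fdk <- function(ps, grid, apodization = "shepp-logan", cutoff = 1,
                provenance = NULL) {
  nf <- dim(ps$frames)[3]
  if (nf < 2) stop("need at least two frames")
  fan <- 2 * asin(min(1, (grid$n[1] * grid$voxel / 2) / ps$geometry$R_F))
  cov <- angular_coverage(ps$timeline$angle)
  if (cov < pi + fan)
    stop(sprintf(paste0("insufficient angular coverage: %.0f degrees ",
                        "covered, %.0f required"),
                 cov * 180 / pi, (pi + fan) * 180 / pi))
  fp <- filter_projections(ps$frames, ps$geometry, apodization, cutoff)
  w <- angular_weights(ps$timeline$angle, warn_empty = FALSE)
  bp <- cpp_backproject(as.numeric(fp$filtered), dim(ps$frames),
                        ps$timeline$angle, w, ps$geometry$R_F, fp$du,
                        grid$n, grid$voxel, grid$origin)
  prov <- if (is.null(provenance))
    list(tag = "Std", n_frames = nf, dose_fraction = ps$dose_fraction,
         apodization = apodization, cutoff = cutoff) else provenance
  vol <- new_volume(array(bp$volume, dim = grid$n), grid$voxel, grid$origin,
                    prov)
  vol$coverage <- array(bp$coverage / nf, dim = grid$n)
  vol
}

#' Gated (phase-correlated) FDK reconstruction
#'
#' Identical chain to \code{\link{fdk}} restricted to the frames selected by
#' \code{bin_mask}; the per-sector angular density re-weighting keeps the
#' reconstructed values unbiased under the non-uniform angle coverage of a
#' gated subset. Sectors containing no selected frames raise a warning and
#' their angular arc is carried by the nearest occupied sector.
#'
#' @param ps a \code{projection_set}; @param bin_mask logical per-frame mask.
#' @inheritParams fdk
#' @param bin_id optional identity recorded in the provenance.
#' @export
fdk_gated <- function(ps, bin_mask, grid, apodization = "shepp-logan",
                      cutoff = 1, bin_id = NULL) {
  if (!any(bin_mask)) stop("all frames masked out")
  sub <- subset_frames(ps, which(bin_mask))
  fp <- filter_projections(sub$frames, sub$geometry, apodization, cutoff)
  w <- angular_weights(sub$timeline$angle, warn_empty = TRUE)
  bp <- cpp_backproject(as.numeric(fp$filtered), dim(sub$frames),
                        sub$timeline$angle, w, sub$geometry$R_F, fp$du,
                        grid$n, grid$voxel, grid$origin)
  nf <- sum(bin_mask)
  vol <- new_volume(array(bp$volume, dim = grid$n), grid$voxel, grid$origin,
                    list(tag = "PC", bin = bin_id, n_frames = nf,
                         fraction = nf / length(bin_mask),
                         apodization = apodization, cutoff = cutoff))
  vol$coverage <- array(bp$coverage / nf, dim = grid$n)
  vol
}

#' Phase-correlated reconstruction series over the cardiac cycle
#'
#' One gated reconstruction per cardiac window inside the chosen
#' respiratory window (a \code{volume4d}).
#'
#' @param ps a \code{projection_set}; @param track a \code{phase_track}.
#' @param gspec a \code{gating_spec}; @param resp_bin respiratory window
#'   index (default 1 = end-expiration under the phase convention used
#'   here).
#' @inheritParams fdk
#' @export
reconstruct_phase_series <- function(ps, track, gspec, grid, resp_bin = 1,
                                     apodization = "shepp-logan", cutoff = 1) {
  bins <- suppressWarnings(assign_bins(track, gspec))
  vols <- vector("list", gspec$n_cardiac_bins)
  counts <- integer(gspec$n_cardiac_bins)
  for (cb in seq_len(gspec$n_cardiac_bins)) {
    m <- bins$joint_mask[, cb, resp_bin]
    counts[cb] <- sum(m)
    vols[[cb]] <- fdk_gated(ps, m, grid, apodization, cutoff,
                            bin_id = c(cardiac = cb, resp = resp_bin))
  }
  structure(list(volumes = vols, frame_counts = counts, resp_bin = resp_bin,
                 gating = gspec, grid = grid),
            class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  cat(sprintf("<volume4d> %d cardiac phases (resp bin %d), frames/bin: %s\n",
              length(x$volumes), x$resp_bin,
              paste(x$frame_counts, collapse = " ")))
  invisible(x)
}
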