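#!/usr/bin/env Rscript
# Derives cardiac and respiratory phases for every frame intrinsically from
# the projections (no ECG, no breathing sensor) and assigns the gating bins
# (four 25% respiratory x ten 10% cardiac windows). Writes the phase track
# as CSV plus a surrogate-signal audit figure.
source("analysis/_common.R")

cfg <- analysis_config()
run_stage(cfg, "gate")

track <- readRDS(file.path(cfg$out_dir, "phase_track.rds"))
cat(sprintf("estimated rates: %.1f bpm cardiac (truth %g), %.1f rpm respiratory (truth %g)\n",
            track$cardiac_rate_bpm, cfg$phantom$heart_rate,
            track$resp_rate_rpm, cfg$phantom$resp_rate))

png(file.path(cfg$out_dir, "surrogates.png"), width = 1000, height = 500)
op <- par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
sel <- track$time <= 3
plot(track$time[sel], track$surrogates$resp_filtered[sel], type = "l",
     xlab = "time (s)", ylab = "a.u.", main = "respiratory surrogate (band-passed)")
plot(track$time[sel], track$surrogates$cardiac_filtered[sel], type = "l",
     xlab = "time (s)", ylab = "a.u.", main = "cardiac surrogate (band-passed)")
par(op); dev.off()
cat("wrote", file.path(cfg$out_dir, "surrogates.png"), "\n")
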