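#!/usr/bin/env Rscript
# Simulates the desk-profile acquisition of the beating mouse-heart phantom:
# 2580 frames (30 s at 86 fps, 10 s/rev) of a 128x96 detector over a 12 mm
# field of view, plus a full-dose Poisson-noise realization. Artifacts and a
# checksummed manifest land in results/pipeline/.
source("analysis/_common.R")

cfg <- analysis_config()
run_stage(cfg, "simulate")

ps <- read_projections(file.path(cfg$out_dir, "projections.rds"))
cat(sprintf("simulated %d frames of %dx%d pixels (%.0f s scan, %.0f rpm gantry)\n",
            dim(ps$frames)[3], dim(ps$frames)[1], dim(ps$frames)[2],
            cfg$geometry$scan_duration, 60 / cfg$geometry$rotation_time))
cat(sprintf("phantom: %g bpm cardiac, %g rpm respiratory\n",
            cfg$phantom$heart_rate, cfg$phantom$resp_rate))
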