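# mococt

Retrospectively gated, motion-compensated cardiac micro-CT — simulation,
reconstruction and evaluation in one package.

## The problem

Coronary CT angiography is routine in patients but extremely hard in mice:
the heart is ~9 mm long, beats at up to 600 bpm under up to 300
respirations per minute, and the left coronary artery tapers from ~400 µm
at its ostium to an average of ~160 µm. Resolving moving structures of that
size needs simultaneously high spatial and temporal resolution, and dose
grows with the fourth power of spatial resolution, so brute force is not an
option. The computational answer is a chain of

1. **intrinsic gating** — cardiac and respiratory phases derived from the
   projection data themselves (no ECG leads, no breathing pillow),
2. **phase-correlated (PC) reconstruction** — FDK filtered backprojection
   `f_PC = X⁻¹_PC q` restricted to frames inside a chosen cardiac ×
   respiratory window (≈2.5 % of the data at the standard Δc = 10 %,
   Δr = 25 % windows), versus the standard `f_Std = X⁻¹ q`,
3. **motion compensation (MoCo)** — cyclic Demons motion-vector fields
   between adjacent cardiac phases, loop-closure corrected, used to warp
   every phase volume to a reference phase and average them:
   `f_MoCo` keeps the temporal resolution of `f_PC` at the noise level of
   `f_Std`,
4. **tensor-based adaptive filtering (TBAF)** — oriented, noise-adaptive
   denoising along the local structure direction.

`mococt` implements this pipeline end-to-end in R (with C++ cores for
projection, backprojection, registration and filtering), together with a
4D analytic mouse-heart phantom and a cone-beam scanner simulator
(source–isocenter 90 mm, source–detector 590 mm, 4×74.8 µm binned pixels,
86 frames/s, 10 s/rev, 5 min ≙ 5 Gy at full scale), so every stage can be
validated against exact ground truth. It is aimed at researchers
developing or teaching gated/motion-compensated CT reconstruction who
need a fully measurable desk-scale testbed.

## Worked example

```r
library(mococt)

# a beating mouse-heart phantom and a reduced desk-scale acquisition
spec <- desk_phantom_spec()                       # 587 bpm, 283 rpm
geom <- desk_geometry(n_cols = 64, n_rows = 48,   # 12 mm FOV, 86 fps
                      scan_duration = 60)         # 5160 frames, 6 revs
ps   <- simulate_scan(spec, geom)                 # exact line integrals
psn  <- apply_noise(ps, dose_fraction = 1, seed = 1)

# intrinsic gating: phases from the projections alone
track <- extract_gating_signals(psn)

# phase-correlated series in the end-expiration window, then MoCo
grid   <- recon_grid(48, 0.2)
series <- suppressWarnings(reconstruct_phase_series(psn, track, gating_spec(),
                                                    grid, resp_bin = 3))
fields <- enforce_cyclicity(estimate_cycle_fields(series))
moco   <- motion_compensate(series, fields, reference_bin = 1)

# dose-reduction study: coronary CNR, phase-correlated vs motion-compensated
res <- suppressWarnings(dose_sweep(ps, track, gating_spec(), grid,
                                   dose_levels_mGy = c(2000, 500),
                                   methods = c("PC", "MoCo"),
                                   seed = 1, resp_bin = 3))
```

Output (about 90 s on one CPU):

```
cardiac  587.0 bpm (true 587), phase RMS 0.008 cycles
respiratory 283.0 rpm (true 283), phase RMS 0.001 cycles
loop-closure residual 0.071 voxels
 dose_mGy method sigma_hu   cnr detectable
     2000     PC    24.90 11.02       TRUE
     2000   MoCo     7.13 33.50       TRUE
      500     PC    55.82  4.55       TRUE
      500   MoCo     9.95 14.32       TRUE
```

Reading it: the gating recovers both physiological rates to ≲0.1 % and the
per-frame phases to ~0.01 cycles; the ten adjacent-phase motion fields
close their cardiac loop to under a tenth of a voxel after the cyclicity
correction; and at every dose level the motion-compensated volume has a
several-fold lower myocardial noise (`sigma_hu`) and correspondingly
higher coronary contrast-to-noise ratio than the phase-correlated
reconstruction built from the same frames — the quantitative content of a
dose-reduction study, with the Rose criterion (CNR ≥ 4) as the
detectability proxy.

The numbered scripts under `analysis/` run the same chain at the full desk
profile (128×96 detector, 96³ volume at 100 µm) stage by stage
(`01_simulate` … `07_report`), writing volumes (NIfTI), phase tracks
(CSV), sweep tables (CSV/JSON), figures (PNG) and a checksummed JSON
manifest per stage under `results/pipeline/`.

## Layout

- `R/`, `src/` — package code (phantom, scanner, gating, recon, moco,
  tbaf, metrics, pipeline) and Rcpp cores.
- `analysis/` — numbered workflow drivers over the package.
- `tests/testthat/` — unit, property and acceptance tests.
- `vignettes/motion-compensated-microct.Rmd` — models, assumptions,
  parameter choices and limitations.
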