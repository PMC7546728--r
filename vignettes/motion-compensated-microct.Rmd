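---
title: "Motion-compensated coronary micro-CT: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-compensated coronary micro-CT: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mococt)
```

## The problem

Imaging coronary arteries in mice is at the edge of what in-vivo micro-CT
can do. A mouse heart is about 9 mm long and 4 mm across, beats at up to
600 bpm under up to 300 respirations per minute, and its left coronary
artery tapers from roughly 400 um at the ostium to an average of about
160 um. Resolving such structures needs both high spatial resolution
(tens of microns) and high temporal resolution (about 10 ms), and the two
fight each other through dose: for a fixed object and noise level, the
dose required grows with the fourth power of spatial resolution, so a
twofold resolution gain costs a sixteenfold dose increase.

`mococt` implements the computational side of a retrospectively gated,
motion-compensated cone-beam micro-CT pipeline for this problem, together
with a dynamic digital mouse-heart phantom and a scanner simulator so that
every stage can be exercised and measured quantitatively without animals
or hardware. The chain is:

1. **phantom4d** — an analytic, time-dependent thorax/heart scene;
2. **scanner** — cone-beam forward projection with Poisson dose modelling;
3. **gating** — intrinsic (image-based) cardiac and respiratory phases;
4. **recon** — FDK filtered backprojection, standard (`f_Std`) and
   phase-correlated (`f_PC`);
5. **moco** — cyclic Demons motion estimation and motion-compensated
   superposition (`f_MoCo`);
6. **tbaf** — structure-tensor adaptive denoising;
7. **metrics / pipeline** — CNR, vessel tracking, the dose sweep, and an
   orchestration layer with manifests (driven by the numbered scripts
   under `analysis/`).

## The phantom

The anatomy is a compound of analytic primitives — axis-aligned
ellipsoids (thorax background, myocardium, ventricular cavities, atria)
and capsule chains (aorta, pulmonary trunk, coronary tree) — each with a
constant attenuation and a priority; where primitives overlap the highest
priority wins (coronary > ventricular blood > myocardium > great
vessels/atria > background). Attenuation can be evaluated exactly at any
point and time, and line integrals through the scene are exact
ray–primitive intersections, so the simulator has no discretization error
of its own.

Tissue values default to +600 HU for all blood-pool compartments (a
blood-pool contrast agent circulates for the whole scan, so enhancement
is temporally constant), +50 HU myocardium and −200 HU thorax mix; these
render sensibly under the conventional display window C = 300 HU,
W = 1500 HU. Water is 0.02/mm at the effective energy; the model is
monochromatic by design and does not attempt beam hardening.

**Cardiac motion.** No murine ventricular waveform is tabulated to the
precision we would need, so contraction is a raised-cosine pulse
occupying a duty fraction of the cycle (default 0.35, peak contraction at
phase 0.175, diastolic plateau for the rest). The ventricular inner radii
contract by `ejection_amplitude` (default 0.25); the wall thickens so
that the myocardial shell volume is conserved *analytically* (the
transverse outer-ellipsoid scale is solved from the cavity volumes), and
a dense-grid integration oracle confirms conservation to well under 2%.
The coronary centerline lies on the epicardial surface and is deformed by
the same transverse scaling — the vessels ride the wall — while vessel
*diameters* are rigid. Atria fill during ventricular systole with a small
counter-phase volume change.

**Respiratory motion.** A raised-cosine craniocaudal translation (default
0.8 mm, inspiratory duty 0.3, so ~70% of the cycle is an end-expiration
plateau) plus a small anterior–posterior displacement of the organ
centres and chest wall (3% scale on centres). Respiration translates but
does not deform the heart, so shell-volume conservation is unaffected.

**Rates.** `phantom_spec()` defaults to the headline 600 bpm / 300 rpm.
The desk scenario `desk_phantom_spec()` uses 587 bpm / 283 rpm: with any
rotation period commensurate with these rates a cardiac bin would sample
the same few gantry angles in every cycle and the physiological signals
would be locked to the gantry angle, which makes both gated
reconstruction and intrinsic gating ill-posed. Real heart and breathing
rates are never exact multiples of the rotation rate; the slightly
detuned defaults reproduce that property deliberately. An optional
seeded, smooth phase-jitter process is available for heart-rate
variability studies and is off by default so that periodicity invariants
hold exactly.

## The scanner model

Geometry follows the physical system: source–isocenter 90 mm,
source–detector 590 mm (magnification 6.56), square detector pixels of
4 × 74.8 um (4×4 binning), 86 frames/s, 10 s per rotation, 300 s per
scan, 5 Gy nominal full-scan dose. The timeline is
`floor(framerate * duration)` frames with angle 2&pi;t/T.

The **desk profile** (`desk_geometry()`) keeps the field of view (12 mm)
and the 86 fps / 10 s-per-rev schedule but reduces the detector to
128×96 binned pixels and the scan to 60 s (5160 frames, 6 revolutions),
with a 96^3 voxel grid at 100 um. Three desk-profile choices deserve
explanation:

* *Rotation speed.* A 1 s/rev desk rotation at 86 fps would repeat the
  same 86 angles every revolution (framerate and rotation commensurate)
  and would place gantry harmonics exactly on 5 and 10 Hz, the
  physiological bands. The desk profile therefore keeps the full
  protocol's 10 s/rev, where each revolution samples 860 distinct angles
  and the relevant gantry harmonics are the ~50th and ~100th, which are
  negligible.
* *Photon budget.* The desk scan is much shorter than the full protocol;
  its per-frame photon budget is raised to 10^6 so that the "full dose"
  desk scan carries the photon statistics of the real 5 Gy acquisition,
  and fractional dose levels mean the same thing in both profiles.
* *Duration.* 60 s rather than a minimal 30 s: at a tenfold dose
  reduction the thinned scan still leaves >10 frames in each of the 40
  joint gating bins, so the dose sweep stays well-posed at desk scale.
  The pipeline's sweep additionally evaluates on a dedicated 48^3 grid at
  0.2 mm, where Demons registration of few-view phase volumes is
  well-conditioned; the full 96^3 grid is used for the full-dose
  reconstruction chain.

Noise is Poisson in transmitted counts, `I0 * dose_fraction * exp(-q)`
per pixel, returned post-log with a 0.5-count floor (a warning flags the
photon-starvation regime below 10 mean air counts). Dose reduction is
realized by uniform frame thinning by default — matching how fractions of
an acquired dataset are reused — with photon-budget scaling as the
alternative mode. Motion is frozen at each frame's timestamp; the 11.7 ms
integration-time blur of the physical detector is not simulated, but a
`supersample` flag averages sub-frame instants for studying it. A
voxel-domain ray-marching projector is included purely as an independent
cross-check of the analytic projector.

## Intrinsic gating

No ECG leads or breathing pillow: both phases come from the projections.

* The **respiratory surrogate** is the row-wise (craniocaudal) centre of
  mass of each frame. The gantry-angle-locked component (static anatomy
  rotating past the detector) is removed by subtracting per-5°-sector
  means over all revolutions; the cleaned signal is band-pass filtered
  (zero-phase Butterworth, order 4) around its dominant spectral peak in
  1–8 Hz, and phase ramps linearly from peak to peak (phase 0 =
  end-inspiration; sub-sample peak times by parabolic interpolation).
* The **cardiac surrogate** is the *total* intensity over the central
  detector rows. The sum of line integrals measures the projected
  attenuation mass, which is invariant under rotation, so the cardiac
  blood-volume modulation adds coherently at every gantry angle —
  region-mean surrogates decohere because opposite heart edges modulate
  with opposite signs. The surrogate is cleaned of the angle-locked
  component and of the respiration-phase-locked component (which removes
  *all* respiratory harmonics); if that stripping also removes the
  cardiac peak the two rates are commensurate and the unstripped
  surrogate is used instead, relying on spectral separation. Phase 0 is
  the cardiac surrogate peak, a constant physiological offset from any
  particular cardiac event; accuracy metrics therefore use the circular
  RMS after removing the best constant offset.

On simulated scans the estimated rates are within a few tenths of a
percent and the circular phase RMS is 0.01–0.035 cycles, against the
0.05-cycle bar the reconstruction bins require.

Gating windows default to the acquisition protocol: four non-overlapping
respiratory windows of 25% and ten cardiac windows of 10%, centres at
(k+0.5)/n, half-open with wrap-around. A joint bin therefore admits 2.5%
of uniformly distributed frames. Under the phase convention above the
end-expiration plateau falls in respiratory bin 3, which is the default
reconstruction window.

## Reconstruction

FDK filtered backprojection: cosine pre-weighting, row-wise ramp
filtering on isocenter-rescaled detector coordinates (discrete band-
limited ramp kernel; Shepp–Logan apodization by default, cutoff at the
detector Nyquist scaled by a `cutoff` factor), and distance-weighted
(`U^2`) backprojection with bilinear detector interpolation. Voxel grids
are isotropic, centred on the isocenter, with world units in mm; rays
leaving the detector contribute zero and a per-voxel coverage fraction is
stored.

Multi-revolution and gated scans are normalized by the local angular
frame density: frames are weighted `1 / (frames per 1° sector)` times the
sector arc, with empty sectors assigning their arc to the nearest
occupied sector (with a warning), and a global factor 1/2 for full-scan
redundancy. This keeps reconstructed values unbiased for arbitrary frame
subsets — a random 2.5% subset reconstructs the same mean value as the
full scan to well under 1% — which is what makes phase-correlated
reconstruction quantitative. Angular coverage is checked in 5° sectors
against the half-turn-plus-fan minimum.

On the static water cylinder the central region reconstructs to 0.02/mm
within 0.3%, the central slice matches an independent 2D fan-beam FBP to
0.01%, reconstruction noise follows 1/sqrt(dose), and gated noise follows
1/sqrt(fraction).

## Motion estimation and compensation

Adjacent cardiac phases are registered with symmetric-force Thirion
demons: 3 pyramid levels (50/30/20 iterations, coarse to fine), Gaussian
fluid regularization of the update (sigma = 1.5 voxels) and diffusion
regularization of the field (sigma = 1.5 voxels), a 1-voxel pre-smoothing
for force computation only (the warps are applied to the raw volumes),
and a 1-voxel per-iteration step cap. The diffusion scale is the one
numerical deviation from the initially intended 1.0 voxel: on gated
desk-scale reconstructions the rougher fields made the first-order loop
correction unstable, while 1.5 voxels keeps translation recovery well
under 0.25 voxel and lets loop closure converge below 0.1 voxel.

Cardiac motion is cyclic, so the composition of all adjacent-phase fields
around the cycle must be the identity. `enforce_cyclicity()` measures the
loop composition and subtracts 1/N of the residual from every field,
damped (0.7) and keeping the best iterate, until the maximum residual
displacement is below 0.1 voxel (the dose sweep relaxes this to 0.25
voxel at strongly reduced dose, where few-view phase volumes yield
rougher fields).

`motion_compensate()` warps every phase volume to the reference phase by
composing adjacent-phase fields along the shorter arc of the cycle —
inverting fields by fixed-point iteration when the short arc runs against
the estimation direction — and averages. Composition along the cycle was
chosen over registering every phase directly to the reference because the
adjacent-phase deformations are small and the cyclicity constraint acts
on exactly these fields; the shorter-arc rule caps interpolation error
accumulation at N/2 compositions. Superposition is an unweighted
intensity average (no Jacobian density compensation). The same machinery
compensates any cyclic phase dimension, so a respiratory-phase series at
a fixed cardiac phase gives the optional cross-respiratory second pass.

With N = 10 cardiac bins inside one respiratory window, `f_MoCo` uses all
of that window's frames and so matches the noise of a standard
(cardiac-ungated) reconstruction of the same window while keeping the
temporal resolution of a single 10% bin. The package verifies this in the
clean configuration — a single 100% respiratory window on a static
phantom, where `f_Std` is the full-scan FDK and the identity holds
photon-for-photon — measuring noise on the difference of two seeded noise
realizations so that structured artifacts common to both cancel.

## Structure-tensor adaptive filtering

The post-filter computes a structure tensor (Gaussian-derivative
gradients at sigma_g = 1 voxel, tensor smoothing at sigma_t = 2 voxels)
and eigen-decomposes it per voxel. Filtering is a 1D Gaussian along the
minor eigenvector — the direction of least intensity variation, along
edges and vessels. (The convention sometimes stated as filtering "along
the largest eigenvalue's direction" would, for a gradient-based tensor,
smooth across edges; the established least-variation convention is used
here.)

The kernel width (base 1.2 voxels, half-length 3) is modulated per voxel
by comparing the smallest eigenvalue against the value expected from
noise alone: the local noise level comes from the MAD of the discrete
Laplacian over 5^3 neighbourhoods (scaled by the stencil energy,
sqrt(42)), and the noise-only eigenvalue response is calibrated once per
scale pair on a seeded unit-variance noise cube. Where even the
least-variation direction carries structure the filter switches itself
off; on noise-dominated voxels it runs at full width. Gating on the
*smallest* eigenvalue rather than the largest is what lets the filter
denoise smooth gradients (their iso-surface direction is noise-only)
instead of switching off on them — and is why it does not staircase where
a range-weighted bilateral filter does. The suite verifies ≥30% noise
reduction at <15% edge-spread growth, mean preservation to 0.1%, a
strictly smaller second-pass reduction (adaptivity), and a smaller
deviation from the best-fit plane than a bundled reference bilateral
filter at matched flat-noise reduction on a noisy ramp.

## Evaluation and the dose sweep

CNR is (mean signal − mean background)/sd(background) with the Rose
criterion CNR ≥ 4 as the stated operational proxy for "identifiable";
reports always carry the flag, not a verdict. The coronary signal ROI is
the dilated ground-truth centerline (simulation privilege); background is
interior myocardium eroded away from boundaries. The dose sweep thins
frames to {2000, 1500, 1000, 500} mGy of the 5000 mGy nominal dose with
per-level derived seeds, reconstructs PC and MoCo at the reference phase,
and tabulates noise, CNR and detectability; on the desk profile MoCo's
CNR exceeds PC's at every level by roughly the expected sqrt(N) noise
factor. Vessel tracking is threshold segmentation plus geodesic front
propagation (26-connectivity), backtracked from locally farthest
endpoints, with diameters from a 3-4-5 chamfer distance transform; for
display, centerlines are conventionally rendered with an artificially
inflated constant radius (1 mm) since real murine coronary calibers are
sub-voxel at display scale. Sliding-thin-slab MIPs provide the
longitudinal view in which the coronary course is readable.

The dose–resolution fourth-power law is measured by
`dose_resolution_experiment()`: a uniform water cylinder, Poisson noise
at three fluences with two replicates, and two reconstruction arms whose
detector pitch, voxel size and ramp cutoff scale together by 2. Scaling
all data dimensions is essential: changing only the reconstruction filter
at fixed detector pitch probes the in-plane third-power law, not the
isotropic fourth-power statement. Because FBP is linear, ROI noise is
exactly proportional to 1/sqrt(fluence) within each arm, and the
equal-noise dose ratio is the mean of (sigma_fine/sigma_coarse)^2 over
matched fluences; the measured factor is 16 within a few percent.

## Problem sizes and what the tests show

The test suite runs everything at reduced desk sizes chosen as the
package's own working points: 64×48- or 48×32-pixel detectors, 20–90 s
scans, 48^3 or 32^3 grids, and 240-angle cylinder scans; the acceptance
measurements use the same sizes. Passing tests demonstrate that the
*algorithms* behave as specified on data whose ground truth is known
exactly. They do not demonstrate animal-scale image quality: the phantom
has no beam hardening, scatter, detector lag or focal-spot blur, its
coronary tree is stylized (one trunk, one bifurcation, small twigs; no
right coronary by default, mirroring that the right coronary was not
expected to be recoverable), and its motion is smooth and, by default,
perfectly periodic. In-vivo visibility rates are physiological outcomes
outside the simulation's scope.

## Known limitations

* Monochromatic, artifact-free physics; no polychromatic spectra.
* Circular trajectory, flat detector, no exact cone-beam correction —
  cone artifacts grow away from the central plane as in any FDK.
* The intrinsic-gating surrogates are validated only against the
  simulator's ground truth; real-data failure modes (arrhythmia, gasping,
  drift) have no analogue here and outlier-beat rejection is not
  implemented.
* Demons registration is intensity-driven and unregularized beyond
  Gaussian smoothing; at the lowest dose levels the estimated fields are
  rough and only the relaxed loop-closure bar applies.
* Projection-domain motion compensation and diffeomorphic (log-domain)
  demons are out of scope.
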