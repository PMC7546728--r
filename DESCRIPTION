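Package: mococt
Title: Retrospectively Gated, Motion-Compensated Cardiac Micro-CT Simulation and Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and reconstruction toolkit for murine coronary micro-CT
    angiography. Provides a parametric 4D digital mouse-heart phantom with
    cardiac and respiratory motion and a contrast-enhanced coronary tree, an
    analytic cone-beam scanner simulator with Poisson dose modelling, intrinsic
    (image-based) cardiorespiratory gating, Feldkamp-Davis-Kress filtered
    backprojection with phase-correlated gated variants, cyclic Demons motion
    estimation with motion-compensated superposition, a structure-tensor
    adaptive denoising filter, and quantitative evaluation utilities (noise,
    contrast-to-noise ratio, sliding-thin-slab maximum intensity projections,
    vessel centerline tracking, dose-reduction sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    signal,
    pracma,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
NeedsCompilation: yes
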