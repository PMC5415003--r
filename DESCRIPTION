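Package: cardiogrid
Title: Finite-Difference Simulation of Cardiac Excitation on Regular Grids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale simulation environment for cardiac electrophysiology
    and other excitable reaction-diffusion media on regular 2D/3D grids.
    Implements monodomain and bidomain tissue models with transversely
    isotropic fibre anisotropy, a 19-point finite-difference diffusion
    stencil whose no-flux boundaries emerge from a tissue indicator
    function, explicit (forward Euler, RK4) and exponential (Rush-Larsen
    and matrix Rush-Larsen, with start-up tabulation) integrators for cell
    kinetics, a full-multigrid solver for the bidomain elliptic equation,
    and a "ring of devices" execution model in which stimulation, feedback,
    measurement and output modules run in declared order once per time
    step. Ships exact-solution verification problems (Bessel-mode decay on
    a disk, bidomain plane waves) with error-norm and convergence-order
    estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    graphics,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
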