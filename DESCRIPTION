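Package: ghostwave
Title: Ghost-Structure Monodomain Solver for Cardiac Action-Potential
    Propagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates cardiac action-potential propagation with the
    monodomain reaction-diffusion model on irregular and moving
    two-dimensional tissue domains using a ghost-structure method: the
    transmembrane potential lives on a regular Cartesian "ghost" grid while
    membrane kinetics live on a triangulated Lagrangian mesh, the two coupled
    through a smoothed four-point delta kernel (immersed-boundary style
    spreading and interpolation plus an L2 projection back to mesh nodes).
    Ships the FitzHugh-Nagumo model, a pluggable cell-model contract with a
    plateau-morphology surrogate ventricular model, third-order TVD
    Runge-Kutta time integration, spiral-wave benchmark fixtures on
    stationary and radially expanding rectangle and circle domains, synthetic
    idealized ventricular sections with healthy and left-bundle-branch-block
    stimulation protocols, and post-processing for activation maps, front
    speeds and spiral-arm widths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
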