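Package: graftflow
Title: Pulsatile Hemodynamics of Competitive Flow in Coronary Bypass Grafts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduced-dimensional (2D planar) computational model of an internal
    thoracic artery to left anterior descending coronary artery (ITA-LAD)
    end-to-side bypass graft with a parametric stenosis in the proximal LAD.
    Provides parametric geometry and triangle mesh generation with tagged
    boundaries, synthetic diastolic-dominant coronary inlet waveforms, a
    transient incompressible Navier-Stokes finite-element solver
    (pressure-correction projection on P1 triangles), wall shear stress
    post-processing (time-averaged wall shear stress and oscillatory shear
    index), analytic Poiseuille and Womersley channel validation oracles, and a
    five-condition competitive-flow study driver comparing graft hemodynamics
    across LAD stenosis degrees.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
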