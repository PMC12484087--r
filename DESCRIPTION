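Package: photodipole
Title: Dual-Pathway Equivalent-Circuit Modelling of Azobenzene
    Photostimulation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and analyses the membrane-potential response of
    passive cells (HEK-293T-like) to membrane-targeted azobenzene
    photoswitches in which a light pulse simultaneously reduces membrane
    capacitance (the opto-mechanical pathway) and shifts the membrane
    surface potential through the isomerization-induced change in
    molecular dipole moment (the dipolar pathway). Implements the
    equivalent-circuit ordinary differential equation with time-varying
    C_m(t) and V_s(t), piecewise-exponential cis-isomer kinetics, a
    leaflet/orientation sign rule for the surface-potential step with
    field-strength amplitude scaling, current-clamp trace metrics and
    holding-potential regression, bounded nonlinear least-squares
    recovery of the photoswitch parameters from recorded traces, and a
    seeded generator of synthetic patch-clamp-like recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
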