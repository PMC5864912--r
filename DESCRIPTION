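Package: porelax
Title: Poroelastic Stress-Relaxation Analysis of Fibrous-Porous Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models a fibrous-porous tissue-engineering scaffold as a long
    transversely isotropic biphasic (poroelastic) cylinder under ramp-and-hold
    axial tension. Provides exact conversions between engineering constants and
    the axisymmetric stiffness matrix, the analytic Bessel-series solution for
    the relaxing load intensity with its characteristic-root spectrum, an
    independent finite-difference solver of the radial consolidation problem,
    Savitzky-Golay signal conditioning of bioreactor force traces, staged
    bounded least-squares estimation of the in-plane modulus, in-plane Poisson
    ratio and gel diffusion time, a seeded synthetic-trace generator emulating
    motor and sensor noise, and a prediction layer for strain-rate sweeps,
    porosity interpolation and peak-load surface fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
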