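Package: muellermc
Title: Polarized Monte Carlo Simulation of Backscattered Mueller-Matrix
    Images of Birefringent Tissue Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic solution of the vector radiative transfer equation
    for slab phantoms that mimic scattering, uniaxially birefringent brain
    white matter.  Photon packets carrying Stokes vectors are propagated
    through a host slab with an embedded box inclusion (crossed fiber
    bundles or an isotropic tumor), exact Mie scattering matrices for
    polydisperse Rayleigh-regime spheres drive the polarization updates,
    and per-pixel Mueller matrices are estimated on a backscattering
    detector grid.  Lu-Chipman polar decomposition with Cloude
    physical-realizability filtering turns the simulated Mueller images
    into maps of depolarization, scalar linear retardance and optic-axis
    azimuth, with region-of-interest contrast statistics and depth-sweep,
    birefringence-sweep and scattering-sweep experiment runners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    grDevices,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
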