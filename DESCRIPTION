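Package: sonotrace
Title: Monte Carlo Light Transport in Ultrasonically Sculpted Virtual
    Optical Waveguides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates light propagation through transparent and turbid
    slabs whose refractive index is continuously modulated by a cylindrical
    ultrasonic standing wave, forming a gradient-index virtual optical
    waveguide in situ. Combines non-linear ray tracing by symplectic
    leapfrog integration of Hamilton's equations with volumetric Monte
    Carlo scattering (Henyey-Greenstein phase function, weight-based
    absorption) and next-event estimation towards a detector disk, with
    unpolarized Fresnel boundary handling. Provides the throughput figures
    of merit used to design such waveguides: insertion loss and gain,
    relative enhancement over an ideal external lens, mechanical-index
    safety bounds, focal-locus extraction from frequency-amplitude sweeps,
    and reproducible experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
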