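Package: pnpore
Title: Poisson-Nernst-Planck Simulation of Ion Transport Through Nanopores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Axisymmetric time-dependent and steady-state Poisson-Nernst-Planck
    (PNP) solver for ion currents through cylindrical and conical nanopores in
    dielectric membranes. The Poisson equation is solved with piecewise-linear
    finite elements over both the electrolyte and the membrane, with fixed
    surface charges entering as natural interface terms, so that screening by
    ions outside the pore is captured without wall Neumann or Donnan boundary
    conditions. Ion transport uses a finite-volume Scharfetter-Gummel scheme
    with piecewise-constant concentrations, a dual time step (Poisson cadence
    set by the membrane RC time, transport by the diffusive stability limit),
    and a steady-state acceleration that alternates time simulation with
    frozen-field steady Nernst-Planck solves and common-mode concentration
    shifts, stopping when per-species plane currents are uniform to 0.5%.
    Includes scenario presets for the surface-charge configurations and conical
    geometries that produce ion current rectification, limiting and
    overlimiting conductances, plus closed-form electrochemical oracles
    (Debye length, Gouy-Chapman double layer, access resistance, membrane RC).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
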