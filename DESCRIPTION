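Package: hemotherm
Title: Conjugate Heat-Transfer Surrogates for Intravascular Waste-Heat
    Exchangers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduced-dimension simulation pipeline for the conjugate
    blood-flow / heat-transfer analysis of fully implantable waste-heat
    sources mounted on the descending aorta.  Provides Carreau-Yasuda
    blood rheology, synthetic pulsatile inlet waveforms, zoned
    finite-volume grids for three heat-exchanger designs (base, fins,
    fins with copper heat guide), a flow-rate-constrained unsteady
    momentum solver, an implicit conjugate advection-diffusion energy
    solver, Lagrangian platelet and red-blood-cell tracking with Stokes
    drag and specular wall reflection, Thermal Exposure Index statistics
    with hyperthermia threshold reporting, and closed-form validation
    oracles (Poiseuille, Womersley, Graetz, transient slab conduction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
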