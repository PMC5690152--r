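Package: protonDMU
Title: Dose-per-Monitor-Unit Calculation for Double-Scattering Proton Beams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the clinical dose per monitor unit (DMU) for a
    double-scattering proton therapy beamline as the product of a measured
    standard DMU and three factors: a beam-spreading-device factor looked up
    from commissioning tables, a patient-specific-device factor obtained from
    paired simplified Monte Carlo (SMC) dose calculations, and an empirical
    field-size correction indexed by the mean aperture radius. Includes a
    simplified Monte Carlo proton transport engine (Gaussian effective source,
    water-equivalent range degradation through range shifter, compensator and
    aperture, Highland multiple Coulomb scattering, depth-dose-curve energy
    deposition on a 2 mm voxel grid with batch statistics), a synthetic
    commissioning-data generator (pristine Bragg curves, spread-out Bragg
    peaks, beam-spreading-device factor tables, field-size output curves),
    patient-specific device geometry models, and field-set comparison
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
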