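Package: rarheo
Title: Resonant Acoustic Rheometry Signal Processing and Coagulation Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational chain for resonant acoustic rheometry (RAR), an
    ultrasound technique that excites and tracks resonant surface waves in a
    small liquid or gel sample to infer its viscoelasticity without contact.
    Provides capillary- and Rayleigh-wave dispersion relations and their
    inversions to surface tension and shear modulus; a synthetic multichannel
    radio-frequency (RF) pulse-echo simulator with planted coagulation
    trajectories; baseline-referenced cross-correlation tracking of surface
    displacement with sub-sample delay estimation; spectrogram construction
    with peak-frequency and peak-width series; extraction of coagulation
    kinetics parameters (initial/final resonant frequency, clotting start and
    end times, clotting duration, final clot shear modulus); and an HDF5
    container format with a command-line pipeline tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    jsonlite,
    yaml,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
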