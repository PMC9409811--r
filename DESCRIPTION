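Package: rfablate
Title: Thermodynamic Simulation and Volume Planning for Unipolar
    Radiofrequency Brain Ablation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Couples an electro-quasistatic potential solver with a
    transient Pennes bioheat solver to predict the 60 degree Celsius
    lesion boundary produced by a unipolar radiofrequency electrode in
    brain tissue. Composes multi-trajectory pull-back lesion plans,
    computes planned ablation volumes from the hemisphere-plus-cylinder
    lesion model, and validates planned volumes against voxel-based
    measurement on synthetic post-ablation images. Includes a synthetic
    phantom generator (grey matter, white matter, hippocampus) so the
    whole pipeline runs without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
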