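Package: spinoload
Title: Lumbar Intersegmental Loads from Sagittal Spinopelvic Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Static musculoskeletal simulation of the standing human trunk in the
    sagittal plane. Builds standing postures from clinical spinopelvic parameters
    (Roussouly lumbar type, sacral slope, pelvic incidence, sagittal vertical axis),
    assembles a weighted rigid-segment chain with lumped trunk muscle actuators
    (multifidus, erector spinae, rectus abdominis), solves the static
    muscle-recruitment problem by minimising a polynomial activation criterion under
    moment equilibrium at every lumbar joint, and decomposes the resulting
    intersegmental forces at L4L5 and L5S1 into axial compression and anterior shear.
    Includes a batch runner for the full 2772-configuration design grid and a
    fixture generator for randomised parameter sets and perturbed anthropometries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
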