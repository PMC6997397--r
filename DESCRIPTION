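Package: spheroTx
Title: Quantification of Tumour Spheroid Response to Radiation and Hyperthermia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based quantification of 3D tumour-spheroid response to radiation,
    hyperthermia and combined treatment. Provides thermal-dose (CEM43) computation,
    a combined linear-quadratic clonogenic-survival model with heat-induced
    radiosensitization, biologically equivalent dose (BEQD) and isoeffect solving,
    spheroid segmentation and 36-diameter morphometry with radial propidium-iodide
    profiles, daily-grid growth-curve assembly with regime classification, and a
    deterministic compartmental spheroid simulator with a two-channel time-lapse
    renderer for fully controlled synthetic studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
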