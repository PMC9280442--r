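Package: dasym
Title: Directional Asymmetry Inference for Bilateral Skeletal Measurements
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting directional asymmetry in bilateral
    skeletal elements measured from 3D landmarks, built around the
    vestigial hindlimbs (pelvis and femur remnants) of limb-reduced
    squamates. Reads and writes MeshLab picked-points (.pp) landmark
    files, converts landmark pairs to element lengths, computes signed
    percent asymmetry per specimen, applies 3-standard-deviation outlier
    screens, and tests each taxon-by-element sample for frequency
    asymmetry (a continuity-corrected chi-square on left- versus
    right-larger counts) and magnitude asymmetry (a paired t-test), with
    Bonferroni correction across tests. Includes a noncentral chi-square
    power analysis for planning sample sizes and a synthetic-specimen
    generator with known asymmetry for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, xml2, grDevices, graphics
Suggests: testthat (>= 3.0.0), withr, jsonlite, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
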