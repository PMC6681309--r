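Package: rhinoct
Title: Nasal Mucosa Morphometry from Micro-CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies swelling of the rodent nasal mucosa from
    micro-computed-tomography volumes. Builds landmark-driven axial and
    coronal slice plans, resamples oblique slices, segments mucosa inside a
    manually drawn nasal-cavity region of interest with a Hounsfield-unit
    bi-threshold, and aggregates per-slice area fractions into a mucosa
    index. Includes a parametric synthetic head phantom with analytic
    ground truth, exact Mann-Whitney U testing, and in-silico drivers for
    dose-response, kinetics, and treatment-comparison experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    oro.nifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
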