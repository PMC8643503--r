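Package: gratiokit
Title: Aggregate g-Ratio Mapping and Lesion-Stratified Biomarker Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for in vivo myelin-integrity analysis with quantitative MRI.
    Forward-simulates magnetization-transfer-weighted spoiled gradient echo
    (SPGR) triplets, multi-shell diffusion MRI and FLAIR-like volumes from
    ground-truth tissue phantoms; estimates MTsat, T1app and MTR maps; fits
    the three-compartment neurite orientation dispersion and density (NODDI)
    model; computes calibrated aggregate g-ratio maps with regional summaries
    for white-matter lesions versus normal-appearing white matter; segments
    hyperintense lesions by robust intensity thresholding; and runs a
    cohort-level plasma neurofilament association analysis with lesion-load
    and g-ratio stratification and exact tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
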