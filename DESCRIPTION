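Package: lesionsurf
Title: Lesion-Aware Cortical Surface Volumetrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Corrects surface-based cortical volume measurements in the
    presence of focal cortical lesions. Provides bit-exact readers and
    writers for FreeSurfer surface, curv, label and annotation files; a
    triangle-mesh geometry kernel with graph geodesics; a non-interactive
    outline-and-fill lesion labeling workflow; lesion-excluded regional
    surface area, thickness and volume statistics with lesion-network
    overlap reports; scan quality and reliability statistics (SNR, CNR,
    ABC/2 lesion volumetry, intraclass correlation); and a deterministic
    synthetic-subject generator with exact ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    RNifti,
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
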