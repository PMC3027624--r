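Package: gliovol
Title: Volumetric Response Assessment of Enhancing Brain Tumors from
    Pre-/Post-Contrast T1 MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Nearly automated quantification of enhancing tumor volume on
    standard T1-weighted pre- and post-contrast brain MRI. Pre-contrast
    volumes are rigidly fused onto the post-contrast grid, the voxelwise
    subtraction map is normalized by the mode of subtraction values inside a
    user-drawn normal-parenchyma region, a per-scan enhancement threshold is
    derived from atlas-detected nasal mucosa (top 5% of corrected mucosa
    values trimmed, threshold = 25% of the remaining maximum), and
    supra-threshold voxels inside a grossly outlined tumor region of interest
    are counted to give enhancing volume in cubic centimetres. Also provides
    conventional RECIST longest-diameter and Macdonald bidimensional
    measurements from lesion masks for side-by-side comparison, a geometric
    phantom generator with exact ground truth (resection-cavity collapse,
    subacute blood, meningeal rim, serial series scenarios), serial-scan
    analysis with region-of-interest transfer, and command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
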