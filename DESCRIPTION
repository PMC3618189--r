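Package: trabmorph
Title: Trabecular Bone Microarchitecture Morphometry and Longitudinal Group Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies trabecular bone microarchitecture from axial grey-level
    image stacks of the distal radius and compares longitudinal change between
    groups. Provides endosteal segmentation, within-mask binarization, region
    growing hole quantification, maximal-inscribed-disc trabecular thickness and
    separation, skeleton-based nodal and branch density, two-visit absolute and
    percent change, short-term precision statistics (RMSCV, ICC), and
    covariate-adjusted between-group inference with Holm step-down correction.
    Includes a synthetic trabecular image generator (Voronoi-edge lattices with
    known ground truth) for validation, and longitudinal slice matching by
    normalized cross-correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
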