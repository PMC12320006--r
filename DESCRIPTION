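Package: neurostates
Title: Neural State Segmentation and Stimulus-Change Alignment for fMRI Time Series
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Data-driven segmentation of multivariate fMRI time series into
    temporally contiguous neural states by greedy boundary search, with
    boundary-strength scoring and data-driven selection of the number of
    states.  Builds per-volume stimulus-change timelines from annotation
    sources (perceptual-hash distances, feature cosine distances, MFCC
    changes, speech on/offsets, pooled event-boundary button presses),
    applies a hemodynamic delay and volume binning, and quantifies
    boundary/annotation alignment by covariate-corrected partial correlation
    against a duration-preserving state-permutation null.  Includes a
    whole-volume searchlight variant with Benjamini-Hochberg FDR correction
    and voxel-level aggregation, plus a synthetic-data generator with planted
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
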