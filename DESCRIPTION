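Package: calima
Title: Lazy Stack Access and Stimulus-Aware Analysis for Two-Photon
    Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolchain for analysing large two-photon calcium imaging
    experiments with a small memory footprint. Imaging stacks spanning
    several raw-binary or multi-frame TIFF files are exposed as a single
    lazily-read four-dimensional tensor with O(1) axis permutation and
    deferred affine value transforms. Stacks carry stimulus metadata
    (presentation sequences, durations, blank periods, analysis-use
    windows) so that every frame can be tagged with the stimulus it was
    acquired under. Includes sub-pixel rigid translation registration by
    Fourier phase correlation with upsampled refinement, black-level and
    per-pixel baseline (F0) estimation for dF/F0 and FRET-ratio signals,
    intensity-peak ROI detection, ImageJ ROI import, derandomised
    per-trial response extraction with PSTHs, and example analyses
    (receptive-field maps from summed Gaussian fields, direction tuning
    curves, sparseness as response skewness). A synthetic experiment
    generator with full ground truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
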