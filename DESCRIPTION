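Package: imsctseg
Title: Cascaded 3D U-Net Segmentation of Intramedullary Spinal Cord Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fully automatic multiclass segmentation of intramedullary
    spinal cord tumors (tumor core, peritumoral edema, syrinx cavity and
    the whole lesion) on co-registered gadolinium-enhanced T1-weighted and
    T2-weighted MRI. Implements a two-stage cascaded pipeline: a 3D U-Net
    localizes the spinal cord on the T2-weighted scan, both contrasts are
    cropped around the predicted cord, and a second multiclass 3D U-Net
    segments the lesion components patch-wise with overlap-averaged
    stitching. Includes NIfTI spatial preprocessing (resampling to a
    standard 1 x 1 x 2 mm grid, centre crop-or-pad, z-score
    normalisation) with invertible transform records, connected-component
    postprocessing by physical volume, segmentation evaluation metrics
    (Dice, detection rates, precision/recall, volume differences), and a
    synthetic two-contrast phantom cohort generator so the complete
    train/infer/evaluate loop runs without clinical data. The 3D
    convolutional network engine (forward and backward passes, Adam,
    cosine-annealed training with early stopping) is implemented in R and
    C++.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
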