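Package: cardiopcso
Title: Predator Crow Search Optimization for Cardiovascular Disease
    Classification and Left-Ventricle Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for cardiovascular-disease risk modelling built around the
    Predator Crow Search Optimization (PCSO) metaheuristic: information-gain
    feature selection, a PCSO-trained dense neural classifier with
    model-agnostic explanations, a modified U-Net for left-ventricle
    segmentation trained with Dice loss, and the surrounding preprocessing
    (Gaussian filtering, z-scoring, outlier flagging, SMOTE balancing,
    augmentation), evaluation metrics and cross-validation harness. Synthetic
    tabular and phantom-image generators provide ground-truthed fixtures so
    the whole pipeline is exercisable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    RNifti,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
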