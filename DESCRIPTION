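Package: replicheck
Title: Replica Detection for Synthetic 3D Neuroimaging Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects memorized training images (replicas) in synthetic 3D
    neuroimaging datasets. Compares each synthetic volume against a training
    set at three complementary levels -- voxel-wise image measures (MAE,
    RMSE, 3D SSIM), feature-embedding measures (RMSE, cosine similarity),
    and segmentation-mask measures (Dice, average surface distance) --
    summarises closeness with a nearest-neighbour distance-ratio statistic,
    and calibrates replica decision thresholds against visual-scoring ground
    truth via balanced-accuracy sweeps and margin-maximizing thresholds.
    Includes a phantom-study simulator that plants exact or perturbed
    replicas with known labels so the whole pipeline can be validated
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
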