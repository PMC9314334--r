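Package: placecode
Title: Noise Correlations and the Accuracy of Hippocampal Spatial Codes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying how trial-to-trial
    noise correlations bound the accuracy of hippocampal place-cell population
    codes on a linear track. Provides a synthetic session generator (Gaussian
    place fields, independent / limited-range / differential noise covariance
    components), calcium event detection from fluorescence traces via wavelet
    denoising, construction of neuron-by-bin-by-trial activity tensors with a
    trial-shuffle null that removes noise correlations, multiclass linear-SVM
    position decoding with inverse-mean-squared-error saturation fitting,
    cross-validated signal/noise/SNR estimators along the local signal
    direction, noise-covariance eigenmode geometry, and place-field
    heterogeneity statistics including the normalized signal variance (NSV).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    MASS,
    e1071,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
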