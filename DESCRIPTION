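Package: sinusct
Title: Structural Analysis of Paranasal Sinus CT Volumes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for structural analysis of paranasal-sinus-like 3D CT
    volumes: a hybrid CNN-transformer multi-class segmenter with
    shifted-window self-attention, a self-supervised 3D convolutional
    autoencoder producing reconstruction residual maps for anomaly
    localization, segmentation-guided structural embeddings from a
    three-channel 3D CNN, Grad-CAM explainability, and Dice/Jaccard/HD95
    evaluation. Includes a procedural generator of sinus CT phantoms with
    ground-truth masks and insertable structural anomalies, a NIfTI
    preprocessing chain (sanitization, isotropic resampling, shape
    standardization, HU windowing, body masking, mask-guided cropping),
    and an end-to-end pipeline runner. All neural-network layers (3D
    convolution, windowed multi-head attention, group/layer normalization,
    transposed convolution) are implemented natively with hand-written
    backpropagation over BLAS matrix products.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
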