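Package: lmppm
Title: Structural Compression of Convolutional Classifiers by Pruning,
    Depthwise Conversion and Multi-Path Expansion
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for structural compression of convolutional image
    classifiers used in plant leaf disease recognition. Networks are
    described as layer graphs on which three composable rewrites operate:
    global channel pruning by an integer divisor N, replacement of standard
    convolutions by depthwise-separable pairs, and expansion of the feature
    extractor into E parallel paths joined by channel concatenation under a
    single classifier. The package builds the OMNet/LMNet family of
    three-branch-parallel (TBP) architectures and a canonical 101-layer
    bottleneck residual classifier, provides exact integer parameter and
    multiply-accumulate accounting with per-layer breakdowns and weight
    histograms, generates deterministic synthetic leaf-disease image folders,
    and includes a small training and evaluation harness (AdamW,
    cross-entropy, macro precision/recall/F1, ROC and PR curves) so the whole
    pipeline can be exercised on the desktop without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics, grDevices, png, yaml, jsonlite
Suggests: testthat (>= 3.0.0), pROC, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
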