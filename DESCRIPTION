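Package: ssfgan
Title: Spectro-Spatial EEG Feature Maps and Auxiliary-Classifier GAN
    Augmentation for Auditory Spatial Attention Decoding
Version: 0.1.0
Authors@R:
    person("ssfgan", "developers", email = "ssfgan@example.org",
           role = c("aut", "cre"))
Description: Tools for decoding the direction (left/right) of auditory
    spatial attention from multichannel EEG. Windowed recordings are turned
    into 28x28 topographic images of alpha-band (8-13 Hz) power via FFT
    band-power estimation, azimuthal-equidistant projection of the
    electrode montage, and Clough-Tocher scattered-data interpolation.
    An auxiliary-classifier GAN, implemented from scratch on base R linear
    algebra, augments these spectro-spatial feature maps and classifies
    attention direction. Includes a ground-truth-known synthetic EEG
    generator with hemispherically lateralized alpha power, an evaluation
    battery (classification metrics, generated-image similarity, noise
    robustness, traditional-augmentation baselines, McNemar's exact test,
    intra-subject cross-validation), and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
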