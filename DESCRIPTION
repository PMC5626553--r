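Package: filotrack
Title: Segmentation, Tracking and Morphodynamic Analysis of Filopodia in
    Fluorescence Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs filopodia from multi-channel fluorescence
    time-lapse stacks of growth cones and other protrusive cells.
    Frames are enhanced with a Laplacian-of-Gaussian filter,
    auto-thresholded, and split into cell body and protrusions by
    iterated erosion/dilation; protrusions are tracked across frames
    with a Hungarian linear-assignment step whose cost combines base
    distance, tip distance and mask overlap. Per-frame metrics include
    end-corrected length, straightness, direction-corrected tip and
    base movement, tip persistence and a panel of fluorescence means
    (projection, tip, thresholded tip, base, predicted pre-formation
    base, body, background). A downstream statistics layer provides
    track summaries, Spearman correlation matrices with Holm
    adjustment, fluorescence-movement cross-correlation profiles with
    hierarchical clustering, an autocorrelation-preserving block
    randomization test, and discrete-time Markov chain null models. A
    synthetic-movie and coupled-time-series generator with analytic
    ground truth makes the whole pipeline testable without microscopy
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    clue,
    tiff,
    zoo,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
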