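Package: leidar
Title: Leading Eigenvector Dynamics Analysis for Multichannel Oscillatory Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a dynamic phase-locking analysis pipeline for
    multichannel oscillatory recordings such as EEG. Signals are band-pass
    filtered, transformed to instantaneous phase via the analytic signal,
    converted to time-resolved phase-locking matrices, and summarised by
    their leading eigenvectors, which are clustered into recurrent
    phase-locking states (the LEiDA approach). Includes occupancy, dwell
    time and transition statistics with permutation-based inference and
    false discovery rate control, graph-theoretic comparison of thresholded
    connectivity networks, a compact one-dimensional convolutional network
    classifier over three feature sets, and a synthetic-data generator with
    planted Markov-switching phase-locking states for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    igraph,
    jsonlite,
    cluster,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
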