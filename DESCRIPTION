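Package: cyclospi
Title: Rapid Single-Pixel Imaging with Cyclic S-Matrix Masks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computational core of rapid single-pixel imaging (SPI) with
    cyclic Hadamard (S-matrix) masks coded on a spinning photomask. Provides
    cyclic binary code constructions (quadratic residue, twin prime,
    m-sequence) whose circulant matrices are S-matrices, Chinese-remainder
    folding of 1D codes into 2D masks, mask-geometry timing calculators
    (transition time, modulation rate, frame rate), a forward acquisition
    simulator with M-fold sub-pixel oversampling and detector noise, and
    FFT-based O(N log N) reconstruction with sub-pixel alignment and fusion
    of the M interleaved datasets, plus an optional total-variation
    compressed-sensing path and synthetic phantom generators.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
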