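Package: sampen2d
Title: Exact and Monte Carlo Estimation of Two-Dimensional Sample Entropy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the two-dimensional sample entropy (SampEn2D) of
    grayscale images by direct template enumeration, and estimates it with
    two fast Monte Carlo subsampling schemes: plain epoch averaging
    (MCSampEn2D) and upper-confidence-bound weighted averaging
    (UCBMCSampEn2D) in which each Monte Carlo epoch receives a softmax
    weight derived from a bandit-style upper confidence bound on its
    reward. Includes a MIX(p) synthetic image generator, an evaluation
    harness for convergence and error experiments, raster image input
    (PNG, TIFF, PGM/PPM), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    png,
    tiff,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
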