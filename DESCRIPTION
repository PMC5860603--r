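Package: sagahmm
Title: Semi-Automated Genome Annotation with Gaussian-Mixture HMMs and
    Minibatch EM
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unsupervised segmentation of multiple real-valued genomic
    signal tracks (e.g. ChIP-seq or DNase-seq fold enrichment) into a
    fixed number of recurring chromatin-state labels. The model is a
    hidden Markov model with diagonal Gaussian-mixture emissions whose
    variances are tied across labels per (track, component), geometric
    segment-length modelling with hard minimum-length and soft
    expected-length constraints, and exact log-domain forward-backward
    and Viterbi inference on fixed-size genome chunks. Training uses
    expectation-maximization either on a fixed region set or in
    minibatch mode (a fresh random region each round), runs multiple
    random starts, and selects the winning parameters by held-out
    validation likelihood. Includes bedGraph/wiggle input, BED4
    annotation output, per-label Kolmogorov-Smirnov goodness-of-fit and
    transcription-start-site precision/recall evaluation, and a
    synthetic-genome simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    optparse,
    rtracklayer,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
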