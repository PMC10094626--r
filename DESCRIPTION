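Package: noveltank
Title: Novel Tank Test Video Tracking and Behavioral Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-animal particle tracking and behavioral phenotyping for the
    zebrafish novel tank test. Loads recorded tank videos as grayscale frame
    stacks, removes the static scene by base-frame subtraction, detects the fish
    with a Difference-of-Gaussians blob detector, and assembles a trajectory
    with rule-based linking (hold on empty frames, nearest-to-last on multiple
    detections, maximum frame-to-frame jump gate, start-frame dropping). From
    the trajectory it computes the standard novel tank readouts: distance moved,
    latency to reach the upper half, and freezing duration. A synthetic scene
    generator renders ground-truth videos (reflection, dropout, distractors,
    noise) so the whole pipeline is testable without recorded data. Companion
    tools implement the study-level statistics (two-way ANOVA with Tukey HSD,
    Wilcoxon rank-sum, label-free proteomics table filtering) and the targeted
    NAD metabolomics arithmetic (monoisotopic masses, inclusion-list m/z,
    ppm matching, protein normalization and NAD(P)+/NAD(P)H ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    tiff,
    png,
    car,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
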