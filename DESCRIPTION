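Package: mgcratio
Title: Ratiometric Blend Coding in a Firing-Rate Model of the Antennal
    Lobe Macroglomerular Complex
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a 60-neuron firing-rate network model of the insect
    antennal lobe macroglomerular complex (two glomeruli, 30 projection
    neurons, 30 inhibitory local neurons) under two local-interneuron wiring
    regimes: symmetric all-to-all inhibition yielding fixed-point attractor
    (winner-takes-all) dynamics, and sparse asymmetric inhibition yielding
    limit-cycle attractor (winnerless-competition-like) dynamics. Provides
    blend-ratio stimulus generators (single pulses, periodic pulse trains,
    plume-like random pulse schedules), time-binned population response
    matrices, cross-correlation and bin-wise discriminant cross-classification
    maps, ratio-specificity bell-curve widths, code-length accuracy curves,
    and principal-component trajectory divergence statistics for quantifying
    how well the projection-neuron population encodes binary odour-blend
    ratios under static and pulsed stimulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
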