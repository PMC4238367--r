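Package: meaconn
Title: Structural-Prior Refinement of Functional Connectivity on High-Density Micro-Electrode Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates functional connectivity of in vitro neuronal networks
    recorded on high-density micro-electrode arrays (64x64 lattice, 42 um
    pitch) and refines it with a structural prior computed from a
    fluorescence image of the culture. The structural prior is built from
    probabilistic directional features (Hough line segments summarised by
    Von Mises mixtures over electrode patches) propagated with a graph heat
    kernel; the functional graph comes from pairwise spike-train
    cross-correlograms with a physiological propagation-velocity filter and
    a spike-dithering significance threshold. Functional peaks are then
    reweighted by shortest-path structural distance, re-thresholded against
    the reweighted null model, and retained versus discarded links are
    characterised with a linear support vector machine. Includes a
    synthetic-data generator producing matched images and spike trains with
    known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    e1071,
    EBImage,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
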