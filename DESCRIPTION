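Package: conpatch
Title: Detection of Spatially Clustered Conserved Sites in Protein Structures
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects spatially clustered, evolutionarily conserved amino-acid
    patches in protein tertiary structures. Site-specific substitution rates
    are estimated from a multiple sequence alignment by empirical-Bayes
    posterior means under a discretized gamma prior on a neighbor-joining
    tree (or imported from Rate4Site output), mapped onto a PDB structure,
    smoothed by a distance-weighted spatial average over 3D neighborhoods,
    and tested for clustering around an anchor point with a Student's t-test
    scanned over window sizes of 1-20 Angstroms. Includes a simulation
    benchmark with planted conserved clusters, permutation null controls and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    bio3d,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
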