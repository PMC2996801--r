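Package: enmfold
Title: Elastic Network Models and Iterative Unfolding for Coarse-Grained
    Metalloprotein Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coarse-grained analysis of protein stability and folding with
    elastic network models, aimed at small metal-binding folds such as
    Cys2His2 zinc fingers. Builds Gaussian network models (GNM) in which
    C-alpha atoms and bound metal ions are network nodes, fits the spring
    constant against experimental B-factors, computes mode-shape profiles and
    normalized residue cross-correlations, simulates unfolding by iteratively
    breaking the noncovalent contact with the largest mean-square distance
    fluctuation, and reports directional slow modes from the anisotropic
    network model (ANM). Includes a synthetic-structure generator (helix,
    strand, hairpin and loop segments plus an optional pseudo-metal node) so
    the whole pipeline is testable without external structure files, and a
    command-line interface over the same functions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
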