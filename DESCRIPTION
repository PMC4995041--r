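Package: epiclone
Title: Vertex-Model Simulation of Clone Growth and Interface Roughness in Epithelia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the growth of marked cell clones in a two-dimensional
    epithelial junction network using a vertex model with patterned cell-bond
    tension, and quantifies the shape of compartment boundaries and clone
    borders with roughness statistics. Balanced network configurations are
    local minima of a work function with cell area elasticity, cell bond line
    tension and cell perimeter elasticity; tissue growth proceeds by stochastic
    cell divisions followed by relaxation with T1 and T2 junction remodeling.
    Includes an in-silico cell-bond ablation assay that reads out relative
    bond tension from the initial recession velocity of the freed vertices,
    generators for segmented-tissue-like fixtures with known ground truth,
    and a JSON/CSV interface with a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    igraph,
    stats,
    utils,
    ggplot2
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
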