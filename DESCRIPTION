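Package: MetastableRSA
Title: Recurrence Structure Analysis of Metastable Multivariate Dynamics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Segments multivariate time series on the unit hypersphere into
    metastable states and transients using recurrence plots and recurrence
    grammars, selects the recurrence ball size by maximizing a Markov
    utility function, pools metastable state clouds across subjects with
    Hausdorff-distance clustering, and projects representative states onto
    anatomical or functional region spaces through mixing matrices.
    Includes ground-truthed synthetic generators: a metastable switching
    surrogate for module-averaged BOLD ensembles and three canonical
    switching dynamical systems (slow-fast hysteresis, intermingled basins,
    and a stochastic heteroclinic cycle on the 3-sphere).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, deSolve, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), igraph, mclust, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
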