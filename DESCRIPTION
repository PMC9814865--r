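Package: confinedrxn
Title: Kinetics of Imperfect Reactions in Confinement
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying reaction kinetics when the reaction is
    imperfect, i.e. requires multiple random encounters between reactants
    before it completes.  Provides builders for fractal and disordered
    networks (Vicsek fractals, dual Sierpinski gaskets, bond-percolation
    clusters, periodic lattices), event-driven continuous-time Monte Carlo
    of random walks with a per-visit reaction probability, exact
    finite-network solvers (mean reaction times by linear solve, Laplace
    transforms and survival functions by eigendecomposition), the
    universal asymptotic survival theory for compact and noncompact
    transport, and Brownian dynamics with sink-type and partially
    reactive (Robin) spherical targets in nontrivial confining domains,
    together with the matching closed-form mean reaction times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    tibble,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
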