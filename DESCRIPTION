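Package: brownsim
Title: Coarse-Grained Brownian and Langevin Dynamics with Fast
    Hydrodynamic Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implicit-solvent simulation of hierarchically composed
    coarse-grained particles ("proteins" built from independently moving
    gestalt units carrying van-der-Waals spheres, screened point charges,
    bonds and hydrodynamic spheres). Supports overdamped Brownian and
    finitely damped Langevin propagation, Rotne-Prager-Yamakawa
    hydrodynamic interactions through a truncated expansion approximation
    with an exact Cholesky oracle, periodic/reflecting/fixed-obstacle
    boundaries and open constant-density reservoir interfaces, plus
    trajectory analysis: mean-squared displacements and diffusion
    coefficients, rotational relaxation, scaling exponents, transport-rate
    fits and dynamic interaction networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    igraph,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
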