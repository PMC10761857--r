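Package: porescape
Title: Pore-Scale Analysis of Bacterial Colonization in Heterogeneous Porous Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to analyse microbial colonization of microfluidic porous
    media composed of transmitting pores (TPs) and dead-end pores (DEPs).
    Discretizes binary pore masks into grains, transmitting and dead-end
    pores with the maximum-inscribed-disk / segregation-index method, solves
    2D steady incompressible Stokes flow and passive-tracer
    advection-diffusion on the pore geometry, quantifies biomass accumulation
    and quorum-sensing reporter activity from time-lapse image stacks, and
    solves a coupled 1D glucose consumption-diffusion / autoinducer-2 model
    that predicts the glucose-limitation length along dead-end pores. A
    synthetic-scene generator produces geometries and multi-channel image
    stacks with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tibble,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    yaml,
    jsonlite,
    tiff,
    png,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
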