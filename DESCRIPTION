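Package: copolarize
Title: Collective Cell-Polarity Simulation on Coupled Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Hybrid stochastic/reaction-diffusion simulator of front-rear
    polarity establishment in single cells, cell doublets and 4-cell groups.
    Membrane-bound Rac and Rho GTPases cycle stochastically and feed back
    bidirectionally on two competing F-actin density fields on a periodic 1D
    membrane domain. Cells interact only across a fixed intercellular
    junction arc where kinetic rates can be amplified and actin growth rates
    modified, constant or dependent on the neighbouring cell's state. The
    package classifies the resulting arrangements of polarity axes
    (co-alignment, collision, misalignment, supracellular, paired, circular)
    and runs outcome-probability screens over coupling families.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
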