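Package: coexsim
Title: Spatially Explicit Food-Web Coextinction Simulation Under Climate
    and Land-Use Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A gridded world of virtual vertebrate species with asymmetric
    logistic climatic niches, assembled into local weighted food webs by
    trophic, allometric and functional-trait rules. Communities are forced
    with monthly climate and yearly land-use change, species disperse on
    the lattice and may adapt their niches, and extinction cascades
    (bottom-up, top-down and disconnection coextinctions) propagate through
    the webs. A matched control run disables all network effects so the
    amplification of primary extinctions by coextinctions can be
    quantified. Includes a synthetic fixture generator producing every
    input the simulator needs (seasonal climate with a secular trend,
    log-normal body masses, taxon-structured trophic levels, prey-predator
    mass-ratio records, and land-use trajectories).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
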