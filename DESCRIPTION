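Package: emocaccess
Title: Modelling Geographic Remoteness from Emergency Obstetric Care
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Raster travel-time modelling of access to emergency obstetric
    care (EmOC) facilities and its relation to maternal mortality. Builds
    per-scenario travel-cost surfaces from land cover, road networks and
    stream barriers; derives stream networks with Strahler orders from a
    digital elevation model (priority-flood pit filling, D8 routing);
    solves multi-source cost distance over the pace grid; disaggregates
    zone-level census populations onto built-infrastructure cells or
    dwelling points; computes a remoteness index (proportion of population
    more than two hours from EmOC) per administrative zone and transport
    by season scenario; and fits a Poisson log-link generalised linear
    model of the maternal mortality ratio on the 2-SD-standardized
    remoteness index and season. Ships a synthetic-landscape generator
    with known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
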