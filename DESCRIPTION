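Package: selfID
Title: Forward-Time Simulation of Selfing-Rate Evolution and
    Inbreeding-Depression Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Individual-based forward-time simulation of the joint evolution
    of a polygenic selfing rate and recessive deleterious mutations in a
    hermaphroditic diploid population, together with measurement tools for
    the standing genetic association between individual selfing rate and
    offspring fitness, and analytic population-level inbreeding-depression
    metrics that incorporate those associations (modifier invasion fitness,
    association-corrected inbreeding depression, and the selection gradient
    on a quantitative selfing trait).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
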