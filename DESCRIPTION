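Package: depmimic
Title: Departure Order, Affiliation and Mimetism in Collective Group Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of collective departures in socially structured animal
    groups. Computes dyadic affiliation from group-scan samples (composite
    sociability index), travel association (inter-departure intervals),
    departure-order position scores (van/centre/rear), group-cohesion
    statistics, distance-category occupancy, and weighted categorical
    assortativity, with node-permutation inference for dyadic regressions and
    Holm-corrected mixed/fixed-effect models. Includes an agent-based
    simulator of group departures under anonymous, affiliative and spatial
    mimetism (log-linear hazards, Gillespie sampling) so that every statistic
    can be validated by parameter recovery on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    lme4,
    lmerTest,
    multcomp,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
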