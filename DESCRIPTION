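Package: antescape
Title: Symmetry Breaking in Collective Ant Escape
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact statistics and agent-based simulators for two-exit escape
    experiments with ants. Provides the exact fair-coin (random self-propelled
    particle) null for the percentage difference in door use, the
    randomness-corrected collective asymmetry statistic, moving-average and
    standard-deviation curve estimation over trial tables, a lattice
    alarm-pheromone escape model, a Vicsek-like alignment escape model in a
    circular arena, and a synthetic trial-table generator with tunable
    beta-binomial over-dispersion.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
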