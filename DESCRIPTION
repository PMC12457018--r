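Package: paceline
Title: Birth Date, Personality and Metabolic Rate Analysis for Seasonally
    Breeding Small Mammals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying pace-of-life covariation between personality
    and energy metabolism in seasonally breeding rodents. Processes
    flow-through (pull-mode) respirometry recordings into resting metabolic
    rate and acute-stress metabolic statistics, estimates individual birth
    dates from early-life body mass by inverting a Gompertz growth curve,
    computes mixed-model repeatabilities (intraclass correlations) with
    parametric-bootstrap confidence intervals and Monte Carlo permutation
    p-values, and fits piecewise structural equation models over a directed
    acyclic graph with d-separation tests and Fisher's C. A synthetic-data
    generator emulating the causal and noise structure of such field studies
    makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
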