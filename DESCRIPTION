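Package: zoonoprior
Title: Fuzzy AHP Prioritization of Climate-Sensitive Zoonoses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational engine for expert-elicitation workshops that rank
    zoonotic diseases by climate sensitivity. Implements crisp and fuzzy
    analytic hierarchy process (AHP/FAHP) weighting of criteria from pairwise
    comparisons on the Saaty linguistic scale, Saaty consistency-ratio gating,
    group aggregation by geometric means, Buckley triangular-fuzzy-number
    weights with centroid defuzzification, question weighting, and
    confidence-adjusted disease scoring with normalized ranked output. A
    seeded synthetic-workshop generator makes the full pipeline testable
    without real elicitation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
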