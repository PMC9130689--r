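Package: geocna
Title: Geoconfigurational Coincidence Analysis of Neighborhood Health Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-value configurational comparative analysis for small-N
    neighborhood (ZCTA-level) health-equity studies. Calibrates raw social
    conditions (including Index of Concentration at the Extremes measures)
    into multi-value factors, defines a persistent binary outcome over
    repeated observations, exhaustively enumerates minimally sufficient
    conditions with consistency/coverage scoring, iteratively lowers the
    consistency threshold, assembles disjunctive solution formulas with
    ambiguity detection, and runs separate analyses for an outcome and its
    negation (causal asymmetry). Includes a synthetic-data generator with
    planted Boolean causal rules for recovery benchmarking and a
    deterministic 43-neighborhood fixture, plus CSV/JSON/GeoJSON input and
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
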