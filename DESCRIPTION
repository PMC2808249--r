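Package: bathyrule
Title: Island-Rule Tests for Body Size Evolution in Deep-Sea Colonists
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for testing whether colonists of the deep-sea benthos show
    island-rule-like convergence in body size relative to their shallow-water
    congeners. Provides depth-based species classification from recorded depth
    ranges, genus-level pairing of deep and shallow log shell sizes under
    several balancing schemes, ordinary-least-squares and standardized-major-
    axis regression of deep on shallow size, a within-genus label-permutation
    test of the SMA statistic, a likelihood-ratio common-slope test across
    clades, a randomization study exposing the false-positive behaviour of the
    standard OLS slope test, and a hierarchical genus/species simulator so that
    every stage is verifiable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
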