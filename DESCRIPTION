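Package: stabeval
Title: Comprehensive Evaluation of Heavy-Metal Soil Stabilization Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-criteria evaluation of the stabilization (immobilization)
    effect of amendments applied to heavy-metal-contaminated farmland soil.
    Implements analytic hierarchy process (AHP) weight derivation from Saaty
    pairwise-comparison matrices (sum-product priority vectors, lambda-max,
    consistency ratio with the standard random-index table), expert-panel
    aggregation with consistency filtering, hierarchical weight composition,
    derived indicator transforms (bio-accumulation factor, available
    heavy-metal reduction rate, reference ratios), three piecewise-linear
    standardized scoring functions (S-type, inverse-S, parabolic/midpoint),
    a weighted composite score with equidistant I-V grading, and a
    grade-difference verdict comparing soil quality before and after
    remediation. Ships a 16-indicator registry, an expert-derived weight
    hierarchy, a pot-experiment reference data set, and deterministic
    generators for synthetic judgment-matrix panels and measurement tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
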