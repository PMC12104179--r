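Package: pccmm
Title: Property-Combination Feature Extraction and Reconstruction for Herbal Formulas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Represents traditional herbal formulas through property-flavor-meridian
    label triplets of their constituent materia medica. Builds the sparse Boolean
    triplet ("PCCMM") measurement matrix mapping formula membership vectors to
    triplet-set vectors, reconstructs candidate formulas from target triplet
    vectors by constrained binary combinatorial optimization with enumeration of
    the full optimal solution pool, separates real formulas from Bernoulli
    pseudo-formulas via t-SNE embeddings, classifies deficiency-syndrome labels
    with a bootstrap nearest-class-mean rule, and mines medication patterns
    (item frequency, apriori association rules, binary distances, phi
    correlations) at both the herb and triplet level. Includes a synthetic-data
    generator emulating pharmacopoeia-scale label statistics so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with numpy and scipy (>= 1.9), available
    as "python" on the PATH, for the default MILP solver backend.
Config/testthat/edition: 3
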