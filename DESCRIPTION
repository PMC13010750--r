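Package: audisem
Title: Semantic Labeling and Machine-Learning Comparison for Audiometric Patient Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A hybrid decision-support pipeline for hearing loss. Derives
    clinical quantities (pure-tone averages, air-bone gaps, evidence
    predicates) from NHANES-style audiometric records, labels patients by
    forward chaining over an editable declarative rule base (hearing loss
    type, severity, laterality, treatment recommendation), maps labels to
    SNOMED CT concept identifiers, and compares the rule-based labels
    against a K-Means clustering baseline by training Random Forest
    classifiers on either labeling strategy. Includes a synthetic cohort
    generator with known generative truth so the whole pipeline is testable
    without any external download, plus CSV and RDF Turtle exporters and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    ranger,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
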