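Package: oncordf
Title: Precision-Oncology Real-World Records as an RDF Knowledge Graph
Version: 0.1.0
Authors@R:
    person("oncordf", "developers", email = "oncordf@example.org",
           role = c("aut", "cre"))
Description: Converts heterogeneous precision-oncology real-world records
    (genetic test reports, structured diagnosis and medication data, drug
    mentions in clinical notes) into a normalized RDF knowledge graph under a
    genetic-testing-ontology-derived schema, and runs two downstream analyses
    on the result: gene-drug association-rule mining (support/confidence)
    and mutation-stratified Kaplan-Meier survival.  A reproducible synthetic
    cohort generator emulates the structure of institutional oncology data
    (demographics, cancer-type mix, partial structured-diagnosis coverage,
    variant-nomenclature mappability, planted gene-drug treatment
    affinities, and a TP53 survival penalty) so that every stage of the
    pipeline is testable without access to protected health information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
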