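Package: ontonet
Title: Modular Clinical Ontology Networks with Rules, Extraction and
    Competency-Question Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building modular clinical ontology networks in the
    style used for Diabetes Mellitus care in Mexico: declarative construction
    of domain ontology modules joined by cross-module meta-relations,
    integration of drug/ATC classifications by class-to-instance demotion,
    external referencing of ICD-10 and SNOMED CT codes as annotations,
    gazetteer-based extraction of candidate triples from clinical note text,
    a forward-chaining rule engine for clinical inference rules (body mass
    index, waist-hip index, biotype banding, basal metabolic rate,
    contraindication alerts), population from structured clinical records,
    a seeded synthetic clinical-record corpus generator, and an evaluation
    harness (SPARQL-subset competency questions, cardinality consistency
    checking, and pitfall linting). Networks round-trip through a
    deterministic Turtle subset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
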