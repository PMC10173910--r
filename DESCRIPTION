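Package: edcbridge
Title: Bridging XLSForm Instruments and REDCap Data Dictionaries with
    Semantic Annotation and Data-Quality Tooling
Version: 0.1.0
Authors@R:
    person("EDC", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for electronic data capture (EDC) workflows that span
    KoBoToolbox-style XLSForm instruments and REDCap projects: bidirectional
    conversion between XLSForm workbooks and REDCap data dictionaries
    (including skip-logic to branching-logic translation and the checkbox
    naming convention), derivation of instruments from ontologies and
    generation of ontologies from instruments (Turtle subset), an embedded
    relational store emulating the REDCap surfaces used by the pipeline, an
    ETL processor for field submissions, a data-quality engine (rule
    validation with a query lifecycle, longitudinal visit calendars, alert
    generation), and usability-survey (CSUQ) scoring with deterministic
    synthetic-data generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    DBI,
    RSQLite,
    jsonlite,
    readxl,
    whisker,
    zip
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
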