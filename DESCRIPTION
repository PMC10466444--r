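Package: omopcdc
Title: Bulk and Incremental Loading of FHIR R4 Resources into OMOP CDM
Version: 0.1.0
Authors@R:
    person("MIRACUM-style ETL", "Maintainers", email = "etl@example.org",
           role = c("aut", "cre"))
Description: An Extract-Transform-Load (ETL) engine that populates an OMOP
    Common Data Model (CDM) v5.3.1 target database from HL7 FHIR R4 resources,
    supporting both full (bulk) reloads and timestamp-based incremental loads
    (change data capture of created, updated and deleted resources). Resource
    identity is tracked in OMOP either through two extra columns
    (fhir_logical_id, fhir_identifier) on every standardized table or through
    per-resource-type mapping tables in a separate schema, so that updates and
    deletions in the source can be replayed as delete-then-reinsert operations
    without duplicating or orphaning rows. Includes a synthetic FHIR data
    generator with configurable create/update/delete churn, an evaluation kit
    that verifies bulk-vs-incremental equivalence and cross-strategy
    equivalence, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
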