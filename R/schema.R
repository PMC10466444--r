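# OMOP CDM v5.3.1 column definitions for the 13 tables this ETL fills.
# Types are SQLite storage classes; dates and datetimes are stored as
# ISO-8601 TEXT. Only columns, primary keys and the foreign keys the engine
# relies on are declared; the full 39-table CDM is out of scope.

OMOP_TABLES <- list(
  person = c(
    person_id = "INTEGER", gender_concept_id = "INTEGER",
    year_of_birth = "INTEGER", month_of_birth = "INTEGER",
    day_of_birth = "INTEGER", birth_datetime = "TEXT",
    race_concept_id = "INTEGER", ethnicity_concept_id = "INTEGER",
    location_id = "INTEGER", provider_id = "INTEGER",
    care_site_id = "INTEGER", person_source_value = "TEXT",
    gender_source_value = "TEXT", gender_source_concept_id = "INTEGER",
    race_source_value = "TEXT", race_source_concept_id = "INTEGER",
    ethnicity_source_value = "TEXT", ethnicity_source_concept_id = "INTEGER"
  ),
  observation_period = c(
    observation_period_id = "INTEGER", person_id = "INTEGER",
    observation_period_start_date = "TEXT",
    observation_period_end_date = "TEXT", period_type_concept_id = "INTEGER"
  ),
  visit_occurrence = c(
    visit_occurrence_id = "INTEGER", person_id = "INTEGER",
    visit_concept_id = "INTEGER", visit_start_date = "TEXT",
    visit_start_datetime = "TEXT", visit_end_date = "TEXT",
    visit_end_datetime = "TEXT", visit_type_concept_id = "INTEGER",
    provider_id = "INTEGER", care_site_id = "INTEGER",
    visit_source_value = "TEXT", visit_source_concept_id = "INTEGER",
    admitting_source_concept_id = "INTEGER", admitting_source_value = "TEXT",
    discharge_to_concept_id = "INTEGER", discharge_to_source_value = "TEXT",
    preceding_visit_occurrence_id = "INTEGER"
  ),
  visit_detail = c(
    visit_detail_id = "INTEGER", person_id = "INTEGER",
    visit_detail_concept_id = "INTEGER", visit_detail_start_date = "TEXT",
    visit_detail_start_datetime = "TEXT", visit_detail_end_date = "TEXT",
    visit_detail_end_datetime = "TEXT",
    visit_detail_type_concept_id = "INTEGER", provider_id = "INTEGER",
    care_site_id = "INTEGER", visit_detail_source_value = "TEXT",
    visit_detail_source_concept_id = "INTEGER",
    admitting_source_value = "TEXT", admitting_source_concept_id = "INTEGER",
    discharge_to_source_value = "TEXT", discharge_to_concept_id = "INTEGER",
    preceding_visit_detail_id = "INTEGER", visit_detail_parent_id = "INTEGER",
    visit_occurrence_id = "INTEGER"
  ),
  condition_occurrence = c(
    condition_occurrence_id = "INTEGER", person_id = "INTEGER",
    condition_concept_id = "INTEGER", condition_start_date = "TEXT",
    condition_start_datetime = "TEXT", condition_end_date = "TEXT",
    condition_end_datetime = "TEXT", condition_type_concept_id = "INTEGER",
    condition_status_concept_id = "INTEGER", stop_reason = "TEXT",
    provider_id = "INTEGER", visit_occurrence_id = "INTEGER",
    visit_detail_id = "INTEGER", condition_source_value = "TEXT",
    condition_source_concept_id = "INTEGER",
    condition_status_source_value = "TEXT"
  ),
  drug_exposure = c(
    drug_exposure_id = "INTEGER", person_id = "INTEGER",
    drug_concept_id = "INTEGER", drug_exposure_start_date = "TEXT",
    drug_exposure_start_datetime = "TEXT", drug_exposure_end_date = "TEXT",
    drug_exposure_end_datetime = "TEXT", verbatim_end_date = "TEXT",
    drug_type_concept_id = "INTEGER", stop_reason = "TEXT",
    refills = "INTEGER", quantity = "REAL", days_supply = "INTEGER",
    sig = "TEXT", route_concept_id = "INTEGER", lot_number = "TEXT",
    provider_id = "INTEGER", visit_occurrence_id = "INTEGER",
    visit_detail_id = "INTEGER", drug_source_value = "TEXT",
    drug_source_concept_id = "INTEGER", route_source_value = "TEXT",
    dose_unit_source_value = "TEXT"
  ),
  measurement = c(
    measurement_id = "INTEGER", person_id = "INTEGER",
    measurement_concept_id = "INTEGER", measurement_date = "TEXT",
    measurement_datetime = "TEXT", measurement_time = "TEXT",
    measurement_type_concept_id = "INTEGER", operator_concept_id = "INTEGER",
    value_as_number = "REAL", value_as_concept_id = "INTEGER",
    unit_concept_id = "INTEGER", range_low = "REAL", range_high = "REAL",
    provider_id = "INTEGER", visit_occurrence_id = "INTEGER",
    visit_detail_id = "INTEGER", measurement_source_value = "TEXT",
    measurement_source_concept_id = "INTEGER", unit_source_value = "TEXT",
    value_source_value = "TEXT"
  ),
  observation = c(
    observation_id = "INTEGER", person_id = "INTEGER",
    observation_concept_id = "INTEGER", observation_date = "TEXT",
    observation_datetime = "TEXT", observation_type_concept_id = "INTEGER",
    value_as_number = "REAL", value_as_string = "TEXT",
    value_as_concept_id = "INTEGER", qualifier_concept_id = "INTEGER",
    unit_concept_id = "INTEGER", provider_id = "INTEGER",
    visit_occurrence_id = "INTEGER", visit_detail_id = "INTEGER",
    observation_source_value = "TEXT",
    observation_source_concept_id = "INTEGER", unit_source_value = "TEXT",
    qualifier_source_value = "TEXT"
  ),
  procedure_occurrence = c(
    procedure_occurrence_id = "INTEGER", person_id = "INTEGER",
    procedure_concept_id = "INTEGER", procedure_date = "TEXT",
    procedure_datetime = "TEXT", procedure_type_concept_id = "INTEGER",
    modifier_concept_id = "INTEGER", quantity = "INTEGER",
    provider_id = "INTEGER", visit_occurrence_id = "INTEGER",
    visit_detail_id = "INTEGER", procedure_source_value = "TEXT",
    procedure_source_concept_id = "INTEGER", modifier_source_value = "TEXT"
  ),
  death = c(
    person_id = "INTEGER", death_date = "TEXT", death_datetime = "TEXT",
    death_type_concept_id = "INTEGER", cause_concept_id = "INTEGER",
    cause_source_value = "TEXT", cause_source_concept_id = "INTEGER"
  ),
  care_site = c(
    care_site_id = "INTEGER", care_site_name = "TEXT",
    place_of_service_concept_id = "INTEGER", location_id = "INTEGER",
    care_site_source_value = "TEXT", place_of_service_source_value = "TEXT"
  ),
  fact_relationship = c(
    domain_concept_id_1 = "INTEGER", fact_id_1 = "INTEGER",
    domain_concept_id_2 = "INTEGER", fact_id_2 = "INTEGER",
    relationship_concept_id = "INTEGER"
  ),
  source_to_concept_map = c(
    source_code = "TEXT", source_concept_id = "INTEGER",
    source_vocabulary_id = "TEXT", source_code_description = "TEXT",
    target_concept_id = "INTEGER", target_vocabulary_id = "TEXT",
    valid_start_date = "TEXT", valid_end_date = "TEXT",
    invalid_reason = "TEXT"
  )
)

# Tables with an ETL-assigned surrogate primary key (id sequences). death is
# keyed by person_id; fact_relationship by its two facts; source_to_concept_map
# is static vocabulary content.
SURROGATE_ID <- c(
  person = "person_id",
  observation_period = "observation_period_id",
  visit_occurrence = "visit_occurrence_id",
  visit_detail = "visit_detail_id",
  condition_occurrence = "condition_occurrence_id",
  drug_exposure = "drug_exposure_id",
  measurement = "measurement_id",
  observation = "observation_id",
  procedure_occurrence = "procedure_occurrence_id",
  care_site = "care_site_id"
)

# Foreign keys the store enforces (SQLite PRAGMA foreign_keys = ON).
OMOP_FKS <- list(
  observation_period = c(person_id = "person"),
  visit_occurrence = c(person_id = "person", care_site_id = "care_site"),
  visit_detail = c(person_id = "person", care_site_id = "care_site",
                   visit_occurrence_id = "visit_occurrence"),
  condition_occurrence = c(person_id = "person",
                           visit_occurrence_id = "visit_occurrence"),
  drug_exposure = c(person_id = "person",
                    visit_occurrence_id = "visit_occurrence"),
  measurement = c(person_id = "person",
                  visit_occurrence_id = "visit_occurrence"),
  observation = c(person_id = "person",
                  visit_occurrence_id = "visit_occurrence"),
  procedure_occurrence = c(person_id = "person",
                           visit_occurrence_id = "visit_occurrence"),
  death = c(person_id = "person")
)

# OMOP domain concept ids used in fact_relationship rows and domain routing.
DOMAIN_TABLE <- c(
  Condition = "condition_occurrence",
  Measurement = "measurement",
  Observation = "observation",
  Procedure = "procedure_occurrence",
  Drug = "drug_exposure"
)
DOMAIN_CONCEPT_ID <- c(
  condition_occurrence = 19L, measurement = 21L, observation = 27L,
  procedure_occurrence = 10L, drug_exposure = 13L
)

# Internal tracking DDL. Under the mapping_tables strategy one tracking table
# per supported resource type lives in a separate `etl_tracking` schema
# (emulated in SQLite by a name prefix); under the columns strategy the two
# tracking columns are appended to every standardized table instead.
TRACKING_COLS <- c(fhir_logical_id = "TEXT", fhir_identifier = "TEXT")

tracking_table_name <- function(resource_type) {
  paste0("etl_tracking_", tolower(resource_type))
}

omop_ddl <- function(strategy) {
  stmts <- character(0)
  for (tab in names(OMOP_TABLES)) {
    cols <- OMOP_TABLES[[tab]]
    if (strategy == "columns") cols <- c(cols, TRACKING_COLS)
    defs <- paste0(names(cols), " ", cols)
    pk <- SURROGATE_ID[tab]
    if (!is.na(pk)) defs[names(cols) == pk] <- paste0(pk, " INTEGER PRIMARY KEY")
    fks <- OMOP_FKS[[tab]]
    for (col in names(fks)) {
      defs <- c(defs, sprintf("FOREIGN KEY (%s) REFERENCES %s(%s)",
                              col, fks[[col]], SURROGATE_ID[fks[[col]]]))
    }
    stmts <- c(stmts, sprintf("CREATE TABLE %s (\n  %s\n)", tab,
                              paste(defs, collapse = ",\n  ")))
    if (strategy == "columns" && tab != "source_to_concept_map") {
      stmts <- c(stmts,
                 sprintf("CREATE INDEX idx_%s_flid ON %s (fhir_logical_id)",
                         tab, tab),
                 sprintf("CREATE INDEX idx_%s_fid ON %s (fhir_identifier)",
                         tab, tab))
    }
  }
  if (strategy == "mapping_tables") {
    for (rt in FHIR_TYPES) {
      tt <- tracking_table_name(rt)
      stmts <- c(stmts, sprintf(
        paste0("CREATE TABLE %s (fhir_logical_id TEXT, fhir_identifier TEXT,",
               " omop_table TEXT, omop_id INTEGER)"), tt),
        sprintf("CREATE INDEX idx_%s_flid ON %s (fhir_logical_id)", tt, tt),
        sprintf("CREATE INDEX idx_%s_row ON %s (omop_table, omop_id)", tt, tt))
    }
  }
  stmts <- c(
    stmts,
    "CREATE TABLE etl_meta (key TEXT PRIMARY KEY, value TEXT)",
    "CREATE TABLE etl_id_sequence (table_name TEXT PRIMARY KEY, next_id INTEGER)",
    paste0("CREATE TABLE etl_medication_cache (fhir_logical_id TEXT PRIMARY KEY,",
           " fhir_identifier TEXT, drug_code TEXT)")
  )
  stmts <- c(stmts,
             "CREATE INDEX idx_care_site_src ON care_site (care_site_source_value)")
  # event tables are scanned by person/visit during cascades
  for (tab in names(OMOP_FKS)) {
    stmts <- c(stmts, sprintf("CREATE INDEX idx_%s_person ON %s (person_id)",
                              tab, tab))
    if ("visit_occurrence_id" %in% names(OMOP_FKS[[tab]])) {
      stmts <- c(stmts, sprintf("CREATE INDEX idx_%s_visit ON %s (visit_occurrence_id)",
                                tab, tab))
    }
  }
  stmts
}
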