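# Deterministic FHIR-to-OMOP semantic mapping for the supported resource-type
# subset. The rules are intentionally compact but preserve the structural
# properties the incremental logic depends on: cross-domain routing (a coded
# event lands in the table of its code's domain), multi-table outputs
# (Patient -> person + observation_period [+ death]; Condition with a stage ->
# primary row + stage observation + reciprocal fact_relationship pair) and
# reference-dependent mapping (drug codes resolved through Medication).

CODING_VOCAB <- c(
  "http://fhir.de/CodeSystem/bfarm/icd-10-gm" = "ICD10GM",
  "http://loinc.org" = "LOINC",
  "http://fhir.de/CodeSystem/bfarm/ops" = "OPS",
  "http://fhir.de/CodeSystem/bfarm/atc" = "ATC",
  "urn:omopcdc:tnm" = "TNM",
  "urn:omopcdc:severity" = "SEVERITY"
)

TYPE_CONCEPT_EHR <- 32817L
GENDER_CONCEPT <- c(male = 8507L, female = 8532L)
VISIT_CONCEPT <- c(IMP = 9201L, AMB = 9202L, ER = 9203L)
REL_HAS_STAGE <- 45754814L   # primary fact -> stage observation
REL_STAGE_OF <- 45754815L    # stage observation -> primary fact

first_coding <- function(codeable) {
  cd <- codeable[["coding"]]
  if (length(cd) == 0L) return(NULL)
  c1 <- cd[[1]]
  sys <- c1[["system"]]
  vocab <- if (!is.null(sys) && sys %in% names(CODING_VOCAB))
    CODING_VOCAB[[sys]] else if (is.null(sys)) "" else sys
  list(code = c1[["code"]], vocabulary = vocab)
}

ref_id <- function(ref) {
  # "Patient/p1" -> "p1"
  if (is.null(ref)) return(NULL)
  r <- ref[["reference"]]
  if (is.null(r)) return(NULL)
  sub("^[^/]*/", "", r)
}

date_part <- function(x) if (is.null(x)) NA_character_ else substr(x, 1, 10)

#' Transform one FHIR envelope into OMOP rows
#'
#' Applies the deterministic mapping rules for the supported resource types:
#'
#' * Patient: 1 person row + 1 observation_period row, plus 1 death row iff
#'   deceased. Patient (and Encounter) outputs are flagged
#'   `requires_upsert = TRUE` — the engine updates them in place instead of
#'   delete-then-reinsert, preserving `person_id`/`visit_occurrence_id` so
#'   referential integrity of dependent rows is never broken.
#' * Encounter: 1 visit_occurrence row (+ 1 care_site if its serviceProvider
#'   organization is new, + 1 visit_detail per location entry).
#' * Condition: 1 row in the table selected by the code's domain (cross-domain
#'   routing) and, iff a stage/severity code is present, 1 auxiliary stage
#'   observation row + 2 reciprocal fact_relationship rows linking it to the
#'   primary row.
#' * Observation: 1 row routed by the code's domain (measurement vs
#'   observation).
#' * Procedure: 1 procedure_occurrence row.
#' * MedicationAdministration / MedicationStatement: 1 drug_exposure row whose
#'   drug code is resolved through the referenced Medication resource.
#' * Medication: no standardized rows; its payload is cached so dependents can
#'   resolve it, and its tracking key is registered.
#'
#' Codes absent from the vocabulary route to `observation` with concept id 0
#' (unmapped, never silently dropped). A dangling Patient or Encounter
#' reference is an error naming the reference; a missing Medication reference
#' degrades to concept id 0 with a warning.
#'
#' In the returned rows, `fact_relationship` fact ids are *local ordinals*
#' (1-based position of the referenced row within this mapping output); the
#' engine substitutes the real surrogate ids at insert time, since new OMOP
#' ids are only assigned when the rows are written.
#'
#' @param envelope A non-deleted [fhir_envelope].
#' @param vocab Vocabulary from [read_vocabulary()].
#' @param db An `omop_db` used to resolve Patient/Encounter/Medication
#'   references.
#' @return A `mapping_output`: list with `rows_by_table` (named list of
#'   data.frames) and `requires_upsert` (TRUE only for Patient/Encounter).
#' @export
map_resource <- function(envelope, vocab, db) {
  stopifnot(inherits(envelope, "fhir_envelope"))
  if (envelope$deleted) {
    stop("map_resource applies to non-deleted envelopes", call. = FALSE)
  }
  refs <- db_resolver(db)
  mo <- map_envelope(envelope, vocab_index(vocab), refs)
  for (w in mo$warnings) warning(w, call. = FALSE)
  finalize_mapping_output(mo, envelope$resource_type)
}

finalize_mapping_output <- function(mo, resource_type) {
  tabs <- vapply(mo$pieces, `[[`, "", "table")
  rows_by_table <- lapply(split(seq_along(mo$pieces), tabs), function(i) {
    data.table::setDF(data.table::rbindlist(
      lapply(mo$pieces[i], `[[`, "row"), fill = TRUE))
  })
  for (fp in mo$fact_pairs) {
    fr <- data.frame(
      domain_concept_id_1 = c(fp$d1, fp$d2),
      fact_id_1 = c(fp$ord1, fp$ord2),
      domain_concept_id_2 = c(fp$d2, fp$d1),
      fact_id_2 = c(fp$ord2, fp$ord1),
      relationship_concept_id = c(REL_HAS_STAGE, REL_STAGE_OF)
    )
    rows_by_table$fact_relationship <-
      rbind(rows_by_table[["fact_relationship"]], fr)
  }
  structure(
    list(rows_by_table = rows_by_table,
         requires_upsert = resource_type %in% c("Patient", "Encounter")),
    class = "mapping_output"
  )
}

# Reference resolver backed by live database queries (one-off public calls;
# the engine builds batched resolvers instead).
db_resolver <- function(db) {
  list(
    person = function(pid) {
      key <- paste0(FHIR_PREFIXES[["Patient"]], "-", pid)
      r <- DBI::dbGetQuery(db$con, person_lookup_sql(db),
                           params = list(k = key))
      if (nrow(r) == 0L) NULL else as.numeric(r$person_id[1])
    },
    visit = function(eid) {
      key <- paste0(FHIR_PREFIXES[["Encounter"]], "-", eid)
      r <- DBI::dbGetQuery(db$con, visit_lookup_sql(db),
                           params = list(k = key))
      if (nrow(r) == 0L) NULL else
        list(visit_occurrence_id = as.numeric(r$visit_occurrence_id[1]),
             person_id = as.numeric(r$person_id[1]))
    },
    medication = function(mid) {
      resolve_medication(paste0("Medication/", mid), db, quiet = TRUE)
    },
    care_site = function(org) NULL
  )
}

person_lookup_sql <- function(db) {
  if (db$strategy == "columns") {
    "SELECT person_id FROM person WHERE fhir_logical_id = :k"
  } else {
    paste("SELECT omop_id AS person_id FROM etl_tracking_patient",
          "WHERE fhir_logical_id = :k AND omop_table = 'person'")
  }
}

visit_lookup_sql <- function(db) {
  if (db$strategy == "columns") {
    "SELECT visit_occurrence_id, person_id FROM visit_occurrence WHERE fhir_logical_id = :k"
  } else {
    paste("SELECT v.visit_occurrence_id, v.person_id FROM visit_occurrence v",
          "JOIN etl_tracking_encounter t ON t.omop_id = v.visit_occurrence_id",
          "AND t.omop_table = 'visit_occurrence' WHERE t.fhir_logical_id = :k")
  }
}

#' Resolve a Medication reference to its drug source code
#'
#' Medication resources produce no standardized rows; their coded content is
#' cached (keyed by tracking id) when they are loaded, in this run or any
#' prior run, so that MedicationAdministration/MedicationStatement resources
#' can resolve their `medicationReference` to a drug code for drug_exposure.
#'
#' @param ref Reference string, e.g. `"Medication/m1"`.
#' @param db An `omop_db`.
#' @param quiet Suppress the warning on an unresolvable reference.
#' @return The drug code as `"vocabulary|code"` (e.g. `"ATC|N02BE01"`), or
#'   `NA_character_` with a warning when the reference cannot be resolved (the
#'   caller then writes a drug_exposure row with concept id 0).
#' @export
resolve_medication <- function(ref, db, quiet = FALSE) {
  mid <- sub("^[^/]*/", "", ref)
  key <- paste0(FHIR_PREFIXES[["Medication"]], "-", mid)
  r <- DBI::dbGetQuery(db$con,
    "SELECT drug_code FROM etl_medication_cache WHERE fhir_logical_id = :k",
    params = list(k = key))
  if (nrow(r) == 0L) {
    if (!quiet) warning("unresolvable medication reference: ", ref,
                        call. = FALSE)
    return(NA_character_)
  }
  r$drug_code[1]
}

# --- core per-envelope mapping (engine-internal representation) -------------
# Returns list(pieces = list(list(table=, row=named list)), fact_pairs =
# list(list(ord1, ord2, d1, d2)), warnings = character()).
map_envelope <- function(e, vidx, refs) {
  p <- e$payload
  pieces <- list()
  fact_pairs <- list()
  warnings <- character(0)
  rt <- e$resource_type

  if (rt == "Patient") {
    gender <- p[["gender"]]
    birth <- p[["birthDate"]]
    deceased <- isTRUE(p[["deceasedBoolean"]]) ||
      !is.null(p[["deceasedDateTime"]])
    yob <- if (is.null(birth)) NA_integer_ else
      as.integer(substr(birth, 1, 4))
    pieces[[1]] <- list(table = "person", row = list(
      gender_concept_id = if (!is.null(gender) &&
                              gender %in% names(GENDER_CONCEPT))
        GENDER_CONCEPT[[gender]] else 0L,
      year_of_birth = yob,
      month_of_birth = if (is.null(birth)) NA_integer_ else
        as.integer(substr(birth, 6, 7)),
      day_of_birth = if (is.null(birth)) NA_integer_ else
        as.integer(substr(birth, 9, 10)),
      birth_datetime = if (is.null(birth)) NA_character_ else
        paste0(birth, "T00:00:00"),
      race_concept_id = 0L, ethnicity_concept_id = 0L,
      person_source_value = e$logical_id,
      gender_source_value = if (is.null(gender)) NA_character_ else gender
    ))
    # placeholder span; recomputed from event dates at job end
    pieces[[2]] <- list(table = "observation_period", row = list(
      observation_period_start_date = date_part(p[["birthDate"]]),
      observation_period_end_date = date_part(p[["birthDate"]]),
      period_type_concept_id = TYPE_CONCEPT_EHR
    ))
    if (deceased) {
      dd <- p[["deceasedDateTime"]]
      pieces[[3]] <- list(table = "death", row = list(
        death_date = date_part(dd),
        death_datetime = dd,
        death_type_concept_id = TYPE_CONCEPT_EHR,
        cause_concept_id = 0L
      ))
    }
  } else if (rt == "Encounter") {
    subj <- ref_id(p[["subject"]])
    if (is.null(subj)) stop("Encounter ", e$logical_id, " has no subject",
                            call. = FALSE)
    person_id <- refs$person(subj)
    if (is.null(person_id)) {
      stop("dangling reference Patient/", subj, " in Encounter ",
           e$logical_id, call. = FALSE)
    }
    cls <- p[["class"]][["code"]]
    start <- p[["period"]][["start"]]
    end <- p[["period"]][["end"]]
    org <- ref_id(p[["serviceProvider"]])
    care_site_id <- if (is.null(org)) NA else refs$care_site(org)
    pieces[[1]] <- list(table = "visit_occurrence", row = list(
      person_id = person_id,
      visit_concept_id = if (!is.null(cls) && cls %in% names(VISIT_CONCEPT))
        VISIT_CONCEPT[[cls]] else 0L,
      visit_start_date = date_part(start), visit_start_datetime = start,
      visit_end_date = date_part(end), visit_end_datetime = end,
      visit_type_concept_id = TYPE_CONCEPT_EHR,
      care_site_id = if (is.null(care_site_id)) NA else care_site_id,
      visit_source_value = if (is.null(cls)) NA_character_ else cls
    ))
    for (loc in p[["location"]]) {
      lstart <- loc[["period"]][["start"]]
      lend <- loc[["period"]][["end"]]
      pieces[[length(pieces) + 1L]] <- list(table = "visit_detail", row = list(
        person_id = person_id,
        visit_detail_concept_id = 0L,
        visit_detail_start_date = date_part(lstart),
        visit_detail_start_datetime = lstart,
        visit_detail_end_date = date_part(lend),
        visit_detail_end_datetime = lend,
        visit_detail_type_concept_id = TYPE_CONCEPT_EHR,
        care_site_id = if (is.null(care_site_id)) NA else care_site_id,
        visit_detail_source_value = ref_id(loc[["location"]]),
        visit_occurrence_id = NA  # filled by the engine (same envelope)
      ))
    }
  } else if (rt == "Medication") {
    # reference target only: no standardized rows
  } else {
    ctx <- event_context(e, refs)
    person_id <- ctx$person_id
    visit_id <- ctx$visit_id
    if (rt == "Condition") {
      coding <- first_coding(p[["code"]])
      route <- route_coding(vidx, coding)
      when <- p[["onsetDateTime"]]
      pieces[[1]] <- event_piece(route$table, route$concept_id, coding,
                                 person_id, visit_id, when, p)
      stage <- stage_coding(p)
      if (!is.null(stage)) {
        sroute <- route_coding(vidx, stage)
        pieces[[2]] <- list(table = "observation", row = list(
          person_id = person_id,
          observation_concept_id = sroute$concept_id,
          observation_date = date_part(when), observation_datetime = when,
          observation_type_concept_id = TYPE_CONCEPT_EHR,
          value_as_string = stage$code,
          visit_occurrence_id = visit_id,
          observation_source_value = src_value(stage)
        ))
        fact_pairs[[1]] <- list(
          ord1 = 1L, ord2 = 2L,
          d1 = unname(DOMAIN_CONCEPT_ID[route$table]),
          d2 = unname(DOMAIN_CONCEPT_ID["observation"])
        )
      }
    } else if (rt == "Observation") {
      coding <- first_coding(p[["code"]])
      route <- route_coding(vidx, coding)
      when <- p[["effectiveDateTime"]]
      val <- p[["valueQuantity"]][["value"]]
      piece <- event_piece(route$table, route$concept_id, coding,
                           person_id, visit_id, when, p)
      if (!is.null(val) && route$table %in% c("measurement", "observation")) {
        piece$row$value_as_number <- as.numeric(val)
        piece$row$unit_source_value <- p[["valueQuantity"]][["unit"]]
      }
      pieces[[1]] <- piece
    } else if (rt == "Procedure") {
      coding <- first_coding(p[["code"]])
      route <- route_coding(vidx, coding)
      when <- p[["performedDateTime"]]
      pieces[[1]] <- event_piece(route$table, route$concept_id, coding,
                                 person_id, visit_id, when, p)
    } else { # MedicationAdministration / MedicationStatement
      mid <- ref_id(p[["medicationReference"]])
      code <- if (is.null(mid)) NA_character_ else refs$medication(mid)
      when <- p[["effectiveDateTime"]]
      concept_id <- 0L
      vocab_code <- NA_character_
      if (!is.na(code)) {
        parts <- strsplit(code, "|", fixed = TRUE)[[1]]
        r <- route_indexed(vidx, parts[2], parts[1])
        if (r$table == "drug_exposure") concept_id <- r$concept_id
        vocab_code <- code
      } else {
        warnings <- c(warnings, paste0(
          "unresolvable medication reference in ", rt, "/", e$logical_id))
      }
      pieces[[1]] <- list(table = "drug_exposure", row = list(
        person_id = person_id,
        drug_concept_id = concept_id,
        drug_exposure_start_date = date_part(when),
        drug_exposure_start_datetime = when,
        drug_exposure_end_date = date_part(when),
        drug_type_concept_id = TYPE_CONCEPT_EHR,
        visit_occurrence_id = visit_id,
        drug_source_value = vocab_code
      ))
    }
  }
  list(pieces = pieces, fact_pairs = fact_pairs, warnings = warnings)
}

event_context <- function(e, refs) {
  p <- e$payload
  subj <- ref_id(p[["subject"]])
  enc <- ref_id(p[["encounter"]])
  if (is.null(enc)) enc <- ref_id(p[["context"]])
  visit_id <- NA
  person_id <- NULL
  if (!is.null(enc)) {
    v <- refs$visit(enc)
    if (is.null(v)) {
      stop("dangling reference Encounter/", enc, " in ", e$resource_type,
           "/", e$logical_id, call. = FALSE)
    }
    visit_id <- v$visit_occurrence_id
    person_id <- v$person_id
  }
  if (!is.null(subj)) {
    pid <- refs$person(subj)
    if (is.null(pid)) {
      stop("dangling reference Patient/", subj, " in ", e$resource_type,
           "/", e$logical_id, call. = FALSE)
    }
    person_id <- pid
  }
  if (is.null(person_id)) {
    stop(e$resource_type, "/", e$logical_id,
         " has neither subject nor encounter reference", call. = FALSE)
  }
  list(person_id = person_id, visit_id = visit_id)
}

route_coding <- function(vidx, coding) {
  if (is.null(coding) || is.null(coding$code)) {
    return(list(table = "observation", concept_id = 0L))
  }
  route_indexed(vidx, coding$code, coding$vocabulary)
}

stage_coding <- function(p) {
  st <- p[["stage"]]
  if (length(st) == 0L) return(NULL)
  sm <- st[[1]][["summary"]]
  if (is.null(sm)) return(NULL)
  first_coding(sm)
}

src_value <- function(coding) {
  if (is.null(coding) || is.null(coding$code)) NA_character_ else coding$code
}

# One coded-event row in its routed table.
event_piece <- function(table, concept_id, coding, person_id, visit_id,
                        when, payload) {
  src <- src_value(coding)
  row <- switch(table,
    condition_occurrence = list(
      person_id = person_id, condition_concept_id = concept_id,
      condition_start_date = date_part(when),
      condition_start_datetime = when,
      condition_type_concept_id = TYPE_CONCEPT_EHR,
      visit_occurrence_id = visit_id,
      condition_source_value = src
    ),
    measurement = list(
      person_id = person_id, measurement_concept_id = concept_id,
      measurement_date = date_part(when), measurement_datetime = when,
      measurement_type_concept_id = TYPE_CONCEPT_EHR,
      visit_occurrence_id = visit_id,
      measurement_source_value = src
    ),
    observation = list(
      person_id = person_id, observation_concept_id = concept_id,
      observation_date = date_part(when), observation_datetime = when,
      observation_type_concept_id = TYPE_CONCEPT_EHR,
      visit_occurrence_id = visit_id,
      observation_source_value = src
    ),
    procedure_occurrence = list(
      person_id = person_id, procedure_concept_id = concept_id,
      procedure_date = date_part(when), procedure_datetime = when,
      procedure_type_concept_id = TYPE_CONCEPT_EHR,
      visit_occurrence_id = visit_id,
      procedure_source_value = src
    ),
    drug_exposure = list(
      person_id = person_id, drug_concept_id = concept_id,
      drug_exposure_start_date = date_part(when),
      drug_exposure_start_datetime = when,
      drug_exposure_end_date = date_part(when),
      drug_type_concept_id = TYPE_CONCEPT_EHR,
      visit_occurrence_id = visit_id,
      drug_source_value = src
    )
  )
  list(table = table, row = row)
}
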