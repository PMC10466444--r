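# Hand-built miniature envelopes used across the unit tests. Timestamps are
# explicit so CDC-window and version-collapse behaviour is deterministic.

TS0 <- "2023-01-01T00:00:00Z"

env_patient <- function(id, ts = TS0, gender = "female",
                        birth = "1950-02-03", deceased = FALSE,
                        identifier = paste0("https://example.org/fhir/patient|",
                                            id, "-id")) {
  payload <- list(
    resourceType = "Patient", id = id,
    identifier = list(list(system = "https://example.org/fhir/patient",
                           value = paste0(id, "-id"))),
    gender = gender, birthDate = birth
  )
  if (deceased) payload$deceasedDateTime <- "2023-02-01T10:00:00"
  fhir_envelope(id, "Patient", ts, payload = payload,
                identifier = identifier)
}

env_encounter <- function(id, pid, ts = TS0, org = "orgA", n_loc = 1,
                          class = "IMP",
                          start = "2023-01-10T08:00:00",
                          end = "2023-01-12T08:00:00") {
  payload <- list(
    resourceType = "Encounter", id = id,
    identifier = list(list(system = "https://example.org/fhir/encounter",
                           value = paste0(id, "-id"))),
    class = list(code = class),
    subject = list(reference = paste0("Patient/", pid)),
    period = list(start = start, end = end),
    serviceProvider = list(reference = paste0("Organization/", org))
  )
  if (n_loc > 0) {
    payload$location <- lapply(seq_len(n_loc), function(l) list(
      location = list(reference = sprintf("Location/ward%d", l)),
      period = list(start = start, end = end)))
  }
  fhir_envelope(id, "Encounter", ts, payload = payload,
                identifier = paste0("https://example.org/fhir/encounter|",
                                    id, "-id"))
}

env_condition <- function(id, pid, eid, ts = TS0, code = "I10",
                          stage = NULL, onset = "2023-01-11T09:00:00") {
  payload <- list(
    resourceType = "Condition", id = id,
    identifier = list(list(system = "https://example.org/fhir/condition",
                           value = paste0(id, "-id"))),
    code = list(coding = list(list(
      system = "http://fhir.de/CodeSystem/bfarm/icd-10-gm", code = code))),
    subject = list(reference = paste0("Patient/", pid)),
    encounter = list(reference = paste0("Encounter/", eid)),
    onsetDateTime = onset
  )
  if (!is.null(stage)) {
    payload$stage <- list(list(summary = list(coding = list(list(
      system = "urn:omopcdc:tnm", code = stage)))))
  }
  fhir_envelope(id, "Condition", ts, payload = payload,
                identifier = paste0("https://example.org/fhir/condition|",
                                    id, "-id"))
}

env_observation <- function(id, pid, eid, ts = TS0, code = "718-7",
                            value = 5.5) {
  payload <- list(
    resourceType = "Observation", id = id,
    code = list(coding = list(list(system = "http://loinc.org",
                                   code = code))),
    subject = list(reference = paste0("Patient/", pid)),
    encounter = list(reference = paste0("Encounter/", eid)),
    effectiveDateTime = "2023-01-11T10:00:00",
    valueQuantity = list(value = value, unit = "arb.unit")
  )
  fhir_envelope(id, "Observation", ts, payload = payload)
}

env_procedure <- function(id, pid, eid, ts = TS0, code = "5-470") {
  payload <- list(
    resourceType = "Procedure", id = id,
    code = list(coding = list(list(
      system = "http://fhir.de/CodeSystem/bfarm/ops", code = code))),
    subject = list(reference = paste0("Patient/", pid)),
    encounter = list(reference = paste0("Encounter/", eid)),
    performedDateTime = "2023-01-11T11:00:00"
  )
  fhir_envelope(id, "Procedure", ts, payload = payload)
}

env_medication <- function(id, ts = TS0, code = "N02BE01") {
  payload <- list(
    resourceType = "Medication", id = id,
    code = list(coding = list(list(
      system = "http://fhir.de/CodeSystem/bfarm/atc", code = code)))
  )
  fhir_envelope(id, "Medication", ts, payload = payload)
}

env_medstatement <- function(id, pid, eid, med, ts = TS0,
                             type = "MedicationStatement") {
  payload <- list(
    resourceType = type, id = id,
    medicationReference = list(reference = paste0("Medication/", med)),
    subject = list(reference = paste0("Patient/", pid)),
    context = list(reference = paste0("Encounter/", eid)),
    effectiveDateTime = "2023-01-11T12:00:00"
  )
  fhir_envelope(id, type, ts, payload = payload)
}

env_deleted <- function(id, type, ts) {
  fhir_envelope(id, type, ts, payload = list(), deleted = TRUE)
}

# A consistent miniature hospital: 2 patients (one deceased), 2 encounters,
# events of every kind, one staged condition, one shared medication.
mini_source <- function() {
  list(
    env_patient("p1", "2023-01-02T08:00:00Z"),
    env_patient("p2", "2023-01-02T09:00:00Z", gender = "male",
                deceased = TRUE),
    env_encounter("e1", "p1", "2023-01-03T08:00:00Z", org = "orgA"),
    env_encounter("e2", "p2", "2023-01-03T09:00:00Z", org = "orgB",
                  n_loc = 2, class = "AMB"),
    env_medication("m1", "2023-01-04T08:00:00Z"),
    env_condition("c1", "p1", "e1", "2023-01-05T08:00:00Z", stage = "261650005"),
    env_condition("c2", "p2", "e2", "2023-01-05T09:00:00Z", code = "E11.9"),
    env_observation("o1", "p1", "e1", "2023-01-05T10:00:00Z"),
    env_observation("o2", "p2", "e2", "2023-01-05T11:00:00Z",
                    code = "72166-2"),
    env_procedure("pr1", "p1", "e1", "2023-01-05T12:00:00Z"),
    env_medstatement("ms1", "p1", "e1", "m1", "2023-01-05T13:00:00Z"),
    env_medstatement("ma1", "p2", "e2", "m1", "2023-01-05T14:00:00Z",
                     type = "MedicationAdministration")
  )
}

fresh_db <- function(strategy = "columns", ...) {
  initialize_schema(tempfile(fileext = ".sqlite"), strategy = strategy, ...)
}

close_db <- function(...) {
  for (db in list(...)) {
    path <- db$path
    omop_close(db)
    unlink(path)
  }
}

bulk_cfg <- function(strategy = "columns") {
  load_config(TRUE, tracking_strategy = strategy)
}

incr_cfg <- function(begin, end, strategy = "columns") {
  load_config(FALSE, begin, end, tracking_strategy = strategy)
}

# Independent oracle for version collapsing: sequential scan keeping, per
# (type, id), the envelope whose timestamp is >= the current best.
collapse_oracle <- function(envelopes) {
  best <- list()
  order_seen <- character(0)
  for (e in envelopes) {
    k <- paste(e$resource_type, e$logical_id)
    cur <- best[[k]]
    if (is.null(cur)) {
      best[[k]] <- e
      order_seen <- c(order_seen, k)
    } else if (as.numeric(e$last_updated) >= as.numeric(cur$last_updated)) {
      best[[k]] <- e
    }
  }
  # output order follows position of the survivor in the input
  survivors <- unname(best[order_seen])
  pos <- vapply(survivors, function(s) {
    which(vapply(envelopes, function(e) identical(e, s), logical(1)))[1]
  }, numeric(1))
  survivors[order(pos)]
}

expect_envelopes_equal <- function(a, b) {
  expect_equal(length(a), length(b))
  for (field in c("logical_id", "resource_type", "identifier")) {
    expect_equal(vapply(a, `[[`, "", field), vapply(b, `[[`, "", field))
  }
  expect_equal(vapply(a, function(e) as.numeric(e$last_updated), 0),
               vapply(b, function(e) as.numeric(e$last_updated), 0))
  expect_equal(vapply(a, function(e) e$deleted, TRUE),
               vapply(b, function(e) e$deleted, TRUE))
  expect_equal(lapply(a, `[[`, "payload"), lapply(b, `[[`, "payload"),
               tolerance = 1e-9)
}
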