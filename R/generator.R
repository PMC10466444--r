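# Synthetic FHIR R4 source data. The generator emulates a hospital's
# MI-I-core-data-set-like resource mix at desk scale: patients with
# encounters, per-encounter coded conditions (some staged), lab observations
# (split across the Measurement and Observation domains), procedures and
# medication statements/administrations resolving through a shared pool of
# Medication resources. Values are random draws from the packaged miniature
# vocabulary — clinical realism is a non-goal; structural realism
# (referential completeness, cross-domain codes, multi-table mappings,
# create/update/delete churn) is the point.

#' Synthetic baseline generator configuration
#'
#' Defaults describe a "3-month" baseline of roughly 20,000 resources:
#' 550 patients, 2 encounters per patient, and per-encounter means of
#' 5 conditions, 7 observations, 2 procedures, 1 medication statement and
#' 1 medication administration, plus a pool of 40 shared Medication
#' resources; 5.7% of patients are deceased and 30% of conditions carry a
#' stage code. Counts per encounter are Poisson draws around the means.
#'
#' @param n_patients Number of Patient resources (exact).
#' @param encounters_per_patient,conditions_per_encounter,
#'   observations_per_encounter,procedures_per_encounter,
#'   medstatements_per_encounter,medadministrations_per_encounter Mean counts.
#' @param n_medications Size of the shared Medication pool.
#' @param deceased_fraction Probability a patient is deceased.
#' @param stage_code_fraction Probability a condition carries a stage code.
#' @param seed Integer RNG seed; identical seed + config give an identical
#'   dataset.
#' @param base_date Date (or string) the baseline span starts.
#' @param span_days Length of the baseline span in days; all baseline
#'   last-updated timestamps fall in `[base_date, base_date + span_days)`.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_patients = 550,
                             encounters_per_patient = 2,
                             conditions_per_encounter = 5,
                             observations_per_encounter = 7,
                             procedures_per_encounter = 2,
                             medstatements_per_encounter = 1,
                             medadministrations_per_encounter = 1,
                             n_medications = 40,
                             deceased_fraction = 0.057,
                             stage_code_fraction = 0.3,
                             seed = 1L,
                             base_date = "2023-01-01",
                             span_days = 90) {
  means <- c(encounters_per_patient, conditions_per_encounter,
             observations_per_encounter, procedures_per_encounter,
             medstatements_per_encounter, medadministrations_per_encounter)
  stopifnot(n_patients >= 0, all(means >= 0),
            deceased_fraction >= 0, deceased_fraction <= 1,
            stage_code_fraction >= 0, stage_code_fraction <= 1,
            span_days > 0)
  structure(
    list(n_patients = n_patients,
         encounters_per_patient = encounters_per_patient,
         conditions_per_encounter = conditions_per_encounter,
         observations_per_encounter = observations_per_encounter,
         procedures_per_encounter = procedures_per_encounter,
         medstatements_per_encounter = medstatements_per_encounter,
         medadministrations_per_encounter = medadministrations_per_encounter,
         n_medications = n_medications,
         deceased_fraction = deceased_fraction,
         stage_code_fraction = stage_code_fraction,
         seed = as.integer(seed),
         base_date = as.Date(base_date),
         span_days = span_days),
    class = "generator_config"
  )
}

#' Daily create/update/delete churn profile
#'
#' Expected CUD frequencies per resource type for one simulated day. The
#' default rates — per 10,000 baseline resources of a type and day: 100
#' creates, 50 updates, 10 deletes — are deliberately arbitrary stand-ins for
#' a real source system's churn profile and fully overridable; integer counts
#' per type may be given instead of rates.
#'
#' @param created_rate,updated_rate,deleted_rate Per-resource daily rates
#'   applied to each type's baseline count (defaults 0.01 / 0.005 / 0.001).
#' @param counts Optional named list
#'   `list(Condition = c(created = 5, updated = 2, deleted = 1), ...)` of
#'   exact integer counts per type, overriding the rates for those types.
#' @param seed Integer RNG seed for the simulator.
#' @return A `cud_profile` list.
#' @export
cud_profile <- function(created_rate = 0.01, updated_rate = 0.005,
                        deleted_rate = 0.001, counts = list(), seed = 1L) {
  stopifnot(created_rate >= 0, updated_rate >= 0, deleted_rate >= 0)
  structure(
    list(created_rate = created_rate, updated_rate = updated_rate,
         deleted_rate = deleted_rate, counts = counts,
         seed = as.integer(seed)),
    class = "cud_profile"
  )
}

rand_ts <- function(n, from, to) {
  # uniform POSIXct in [from, to), second precision (source timestamps are
  # serialized without fractional seconds)
  structure(floor(as.numeric(from) +
                    runif(n) * (as.numeric(to) - as.numeric(from))),
            class = c("POSIXct", "POSIXt"), tzone = "UTC")
}

iso_dt <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

identifier_for <- function(type, id) {
  list(list(system = paste0("https://example.org/fhir/", tolower(type)),
            value = paste0(id, "-id")))
}

#' Generate a synthetic FHIR baseline dataset
#'
#' Produces a referentially complete collection of envelopes (every subject,
#' encounter, serviceProvider and medication reference resolves within the
#' collection), deterministic under the config seed, with codes drawn from
#' the packaged miniature vocabulary and last-updated timestamps uniform over
#' the baseline span.
#'
#' @param config A [generator_config].
#' @param vocab Vocabulary from [read_vocabulary()].
#' @return List of [fhir_envelope] objects (Patients first, then Encounters,
#'   Medications and events).
#' @export
generate_baseline <- function(config = generator_config(),
                              vocab = read_vocabulary()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  from <- as.POSIXct(paste(config$base_date, "00:00:00"), tz = "UTC")
  to <- from + config$span_days * 86400
  pool <- vocab_pools(vocab)
  envs <- list()
  chunks <- list()  # per-encounter event lists, flattened once at the end
  n_orgs <- max(3L, round(config$n_patients / 60))

  # medication pool
  med_ids <- sprintf("m%04d", seq_len(config$n_medications))
  for (i in seq_along(med_ids)) {
    code <- sample(pool$drug, 1L)
    payload <- list(
      resourceType = "Medication", id = med_ids[i],
      identifier = identifier_for("Medication", med_ids[i]),
      code = list(coding = list(list(
        system = "http://fhir.de/CodeSystem/bfarm/atc", code = code)))
    )
    envs[[length(envs) + 1L]] <- fhir_envelope(
      med_ids[i], "Medication", rand_ts(1, from, to),
      identifier = first_identifier(payload), payload = payload)
  }

  counter <- new.env(); counter$n <- 0L
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("p%05d", p)
    deceased <- runif(1) < config$deceased_fraction
    birth <- as.Date("1940-01-01") + floor(runif(1, 0, 75 * 365))
    payload <- list(
      resourceType = "Patient", id = pid,
      identifier = identifier_for("Patient", pid),
      gender = sample(c("female", "male"), 1L),
      birthDate = format(birth, "%Y-%m-%d")
    )
    if (deceased) {
      payload$deceasedDateTime <- iso_dt(rand_ts(1, from, to))
    }
    envs[[length(envs) + 1L]] <- fhir_envelope(
      pid, "Patient", rand_ts(1, from, to),
      identifier = first_identifier(payload), payload = payload)

    n_enc <- rpois(1, config$encounters_per_patient)
    for (k in seq_len(n_enc)) {
      eid <- sprintf("%s-e%d", pid, k)
      enc_start <- rand_ts(1, from, to - 7 * 86400)
      enc_end <- enc_start + runif(1, 1, 7) * 86400
      org <- sprintf("org%02d", sample.int(n_orgs, 1L))
      n_loc <- sample(0:2, 1L)
      locs <- lapply(seq_len(n_loc), function(l) list(
        location = list(reference = sprintf("Location/ward%d", l)),
        period = list(start = iso_dt(enc_start + (l - 1) * 3600),
                      end = iso_dt(enc_end))
      ))
      payload <- list(
        resourceType = "Encounter", id = eid,
        identifier = identifier_for("Encounter", eid),
        class = list(code = sample(c("IMP", "AMB"), 1L, prob = c(0.6, 0.4))),
        subject = list(reference = paste0("Patient/", pid)),
        period = list(start = iso_dt(enc_start), end = iso_dt(enc_end)),
        serviceProvider = list(reference = paste0("Organization/", org))
      )
      if (n_loc > 0) payload$location <- locs
      envs[[length(envs) + 1L]] <- fhir_envelope(
        eid, "Encounter", rand_ts(1, from, to),
        identifier = first_identifier(payload), payload = payload)

      chunks[[length(chunks) + 1L]] <-
        event_envelopes(config, pool, counter, pid, eid,
                        enc_start, enc_end, med_ids, from, to)
    }
  }
  c(envs, do.call(c, c(chunks, list(list())))) # flatten once, O(n)
}

vocab_pools <- function(vocab) {
  list(
    condition = vocab$source_code[vocab$source_vocabulary == "ICD10GM"],
    lab = vocab$source_code[vocab$source_vocabulary == "LOINC"],
    procedure = vocab$source_code[vocab$source_vocabulary == "OPS"],
    drug = vocab$source_code[vocab$source_vocabulary == "ATC"],
    stage = vocab$source_code[vocab$source_vocabulary %in%
                                c("TNM", "SEVERITY")],
    stage_vocab = vocab$source_vocabulary[vocab$source_vocabulary %in%
                                            c("TNM", "SEVERITY")]
  )
}

event_envelopes <- function(config, pool, counter, pid, eid,
                            enc_start, enc_end, med_ids, from, to) {
  out <- list()
  mk_id <- function(prefix) {
    counter$n <- counter$n + 1L
    sprintf("%s%07d", prefix, counter$n)
  }
  subject <- list(reference = paste0("Patient/", pid))
  encounter <- list(reference = paste0("Encounter/", eid))
  # one vectorized draw + format per encounter, consumed one by one
  n_ev <- rpois(5, c(config$conditions_per_encounter,
                     config$observations_per_encounter,
                     config$procedures_per_encounter,
                     config$medstatements_per_encounter,
                     config$medadministrations_per_encounter))
  whens <- iso_dt(rand_ts(sum(n_ev), enc_start, enc_end))
  lus <- rand_ts(sum(n_ev), from, to)
  w_i <- 0L
  when <- function() {
    w_i <<- w_i + 1L
    whens[w_i]
  }
  lu <- function() lus[w_i]

  for (j in seq_len(n_ev[1])) {
    id <- mk_id("c")
    payload <- list(
      resourceType = "Condition", id = id,
      identifier = identifier_for("Condition", id),
      code = list(coding = list(list(
        system = "http://fhir.de/CodeSystem/bfarm/icd-10-gm",
        code = sample(pool$condition, 1L)))),
      subject = subject, encounter = encounter,
      onsetDateTime = when()
    )
    if (runif(1) < config$stage_code_fraction) {
      k <- sample.int(length(pool$stage), 1L)
      sys <- if (pool$stage_vocab[k] == "TNM") "urn:omopcdc:tnm" else
        "urn:omopcdc:severity"
      payload$stage <- list(list(summary = list(coding = list(list(
        system = sys, code = pool$stage[k])))))
    }
    out[[length(out) + 1L]] <- fhir_envelope(
      id, "Condition", lu(),
      identifier = first_identifier(payload), payload = payload)
  }
  for (j in seq_len(n_ev[2])) {
    id <- mk_id("o")
    payload <- list(
      resourceType = "Observation", id = id,
      identifier = identifier_for("Observation", id),
      code = list(coding = list(list(
        system = "http://loinc.org", code = sample(pool$lab, 1L)))),
      subject = subject, encounter = encounter,
      effectiveDateTime = when(),
      valueQuantity = list(value = round(runif(1, 0.1, 200), 1),
                           unit = "arb.unit")
    )
    out[[length(out) + 1L]] <- fhir_envelope(
      id, "Observation", lu(),
      identifier = first_identifier(payload), payload = payload)
  }
  for (j in seq_len(n_ev[3])) {
    id <- mk_id("pr")
    payload <- list(
      resourceType = "Procedure", id = id,
      identifier = identifier_for("Procedure", id),
      code = list(coding = list(list(
        system = "http://fhir.de/CodeSystem/bfarm/ops",
        code = sample(pool$procedure, 1L)))),
      subject = subject, encounter = encounter,
      performedDateTime = when()
    )
    out[[length(out) + 1L]] <- fhir_envelope(
      id, "Procedure", lu(),
      identifier = first_identifier(payload), payload = payload)
  }
  med_event <- function(type, prefix) {
    id <- mk_id(prefix)
    payload <- list(
      resourceType = type, id = id,
      identifier = identifier_for(type, id),
      medicationReference = list(
        reference = paste0("Medication/", sample(med_ids, 1L))),
      subject = subject, context = encounter,
      effectiveDateTime = when()
    )
    fhir_envelope(id, type, lu(),
                  identifier = first_identifier(payload), payload = payload)
  }
  for (j in seq_len(n_ev[4])) {
    out[[length(out) + 1L]] <- med_event("MedicationStatement", "ms")
  }
  for (j in seq_len(n_ev[5])) {
    out[[length(out) + 1L]] <- med_event("MedicationAdministration", "ma")
  }
  out
}

#' Simulate one day of create/update/delete churn
#'
#' Builds a delta collection on top of a baseline: *creates* are new
#' resources referencing existing (live) patients, encounters and
#' medications; *updates* re-emit existing resources with one observably
#' modified payload field; *deletes* re-emit resources with `deleted = TRUE`
#' and an empty payload. Deleting a Patient or Encounter additionally emits
#' deletion envelopes for all dependent resources, and deleting a Medication
#' for the statements/administrations referencing it, so that the
#' baseline-plus-delta collection stays referentially complete (cascades are
#' reported beyond the requested per-type counts). All delta timestamps lie
#' within `day`, strictly after every baseline timestamp.
#'
#' @param baseline Envelope list from [generate_baseline()].
#' @param profile A [cud_profile].
#' @param day `Date` (or string) of the simulated day; must start after the
#'   latest baseline timestamp.
#' @param vocab Vocabulary from [read_vocabulary()].
#' @return List of delta [fhir_envelope] objects ordered by timestamp.
#' @export
simulate_day <- function(baseline, profile = cud_profile(),
                         day, vocab = read_vocabulary()) {
  stopifnot(inherits(profile, "cud_profile"))
  set.seed(profile$seed)
  day_start <- as.POSIXct(paste(as.Date(day), "00:00:00"), tz = "UTC")
  day_end <- day_start + 86400
  if (length(baseline)) {
    last_base <- max(envelope_field(baseline, "last_updated", "numeric"))
    if (as.numeric(day_start) <= last_base) {
      stop("day must start strictly after every baseline timestamp",
           call. = FALSE)
    }
  }
  pool <- vocab_pools(vocab)
  types <- envelope_field(baseline, "resource_type")
  ids <- envelope_field(baseline, "logical_id")
  index <- build_reference_index(baseline)

  n_for <- function(type, what, rate) {
    cnt <- profile$counts[[type]]
    if (!is.null(cnt) && what %in% names(cnt)) return(as.integer(cnt[[what]]))
    round(rate * sum(types == type))
  }

  # --- deletions (chosen first so creates/updates avoid dead references) ---
  del_ids <- character(0)
  for (type in FHIR_TYPES) {
    n <- n_for(type, "deleted", profile$deleted_rate)
    candidates <- setdiff(ids[types == type], del_ids)
    if (n > length(candidates)) {
      stop("requested ", n, " deletions of ", type, " but only ",
           length(candidates), " live resources exist", call. = FALSE)
    }
    if (n > 0) del_ids <- c(del_ids, sample(candidates, n))
  }
  del_ids <- cascade_closure(del_ids, ids, types, index)
  live <- !(ids %in% del_ids)

  delta <- list()
  for (i in which(ids %in% del_ids)) {
    delta[[length(delta) + 1L]] <- fhir_envelope(
      ids[i], types[i], rand_ts(1, day_start, day_end),
      identifier = baseline[[i]]$identifier, payload = list(), deleted = TRUE)
  }

  # --- updates: one observable payload change, same logical id -------------
  for (type in FHIR_TYPES) {
    n <- n_for(type, "updated", profile$updated_rate)
    candidates <- which(types == type & live)
    n <- min(n, length(candidates))
    for (i in sample(candidates, n)) {
      e <- baseline[[i]]
      e$payload <- mutate_payload(e$payload, type, pool)
      e$last_updated <- rand_ts(1, day_start, day_end)
      delta[[length(delta) + 1L]] <- e
    }
  }

  # --- creates: new resources referencing live patients/encounters/meds ---
  live_pat <- ids[types == "Patient" & live]
  live_enc <- ids[types == "Encounter" & live]
  live_med <- ids[types == "Medication" & live]
  counter <- new.env(); counter$n <- 0L
  mk_id <- function(prefix) {
    counter$n <- counter$n + 1L
    sprintf("d-%s%06d", prefix, counter$n)
  }
  new_pat <- character(0); new_enc <- character(0)
  for (type in FHIR_TYPES) {
    n <- n_for(type, "created", profile$created_rate)
    if (n == 0) next
    for (j in seq_len(n)) {
      delta[[length(delta) + 1L]] <- create_resource(
        type, mk_id, pool, live_pat, live_enc, live_med,
        new_pat, new_enc, day_start, day_end)
      created <- delta[[length(delta)]]
      if (type == "Patient") {
        new_pat <- c(new_pat, created$logical_id)
        live_pat <- c(live_pat, created$logical_id)
      }
      if (type == "Encounter") {
        new_enc <- c(new_enc, created$logical_id)
        live_enc <- c(live_enc, created$logical_id)
      }
      if (type == "Medication") live_med <- c(live_med, created$logical_id)
    }
  }
  delta[order(envelope_field(delta, "last_updated", "numeric"))]
}

# id -> ids of resources that reference it (children)
build_reference_index <- function(baseline) {
  idx <- new.env(parent = emptyenv())
  add <- function(parent, child) {
    assign(parent, c(get0(parent, envir = idx, ifnotfound = character(0)),
                     child), envir = idx)
  }
  for (e in baseline) {
    p <- e$payload
    for (field in c("subject", "encounter", "context",
                    "medicationReference")) {
      r <- ref_id(p[[field]])
      if (!is.null(r)) add(r, e$logical_id)
    }
  }
  idx
}

cascade_closure <- function(del_ids, ids, types, index) {
  out <- unique(del_ids)
  queue <- out
  while (length(queue)) {
    nxt <- character(0)
    for (id in queue) {
      children <- get0(id, envir = index, ifnotfound = character(0))
      nxt <- c(nxt, setdiff(children, out))
    }
    nxt <- unique(nxt)
    out <- c(out, nxt)
    queue <- nxt
  }
  out
}

mutate_payload <- function(p, type, pool) {
  switch(type,
    Patient = {
      p$gender <- if (identical(p$gender, "female")) "male" else "female"
      p
    },
    Encounter = {
      p$class$code <- if (identical(p$class$code, "IMP")) "AMB" else "IMP"
      p
    },
    Medication = {
      p$code$coding[[1]]$code <- resample_code(pool$drug,
                                               p$code$coding[[1]]$code)
      p
    },
    Condition = {
      p$code$coding[[1]]$code <- resample_code(pool$condition,
                                               p$code$coding[[1]]$code)
      p
    },
    Observation = {
      p$valueQuantity$value <- round(runif(1, 0.1, 200), 1)
      p
    },
    Procedure = {
      p$code$coding[[1]]$code <- resample_code(pool$procedure,
                                               p$code$coding[[1]]$code)
      p
    },
    {
      p$effectiveDateTime <- sub("T.*", "T12:00:00", p$effectiveDateTime)
      p
    }
  )
}

resample_code <- function(pool, current) {
  alt <- setdiff(pool, current)
  if (length(alt) == 0L) current else sample(alt, 1L)
}

create_resource <- function(type, mk_id, pool, live_pat, live_enc, live_med,
                            new_pat, new_enc, day_start, day_end) {
  ts <- rand_ts(1, day_start, day_end)
  when <- iso_dt(rand_ts(1, day_start, day_end))
  if (type == "Patient") {
    id <- mk_id("p")
    payload <- list(
      resourceType = "Patient", id = id,
      identifier = identifier_for("Patient", id),
      gender = sample(c("female", "male"), 1L),
      birthDate = format(as.Date("1940-01-01") + floor(runif(1, 0, 75 * 365)),
                         "%Y-%m-%d"))
    return(fhir_envelope(id, type, ts,
                         identifier = first_identifier(payload),
                         payload = payload))
  }
  if (type == "Encounter") {
    if (length(live_pat) == 0L) stop("no live patients to reference",
                                     call. = FALSE)
    id <- mk_id("e")
    payload <- list(
      resourceType = "Encounter", id = id,
      identifier = identifier_for("Encounter", id),
      class = list(code = sample(c("IMP", "AMB"), 1L)),
      subject = list(reference = paste0("Patient/", sample(live_pat, 1L))),
      period = list(start = when, end = when),
      serviceProvider = list(reference = "Organization/org01"))
    return(fhir_envelope(id, type, ts,
                         identifier = first_identifier(payload),
                         payload = payload))
  }
  if (type == "Medication") {
    id <- mk_id("m")
    payload <- list(
      resourceType = "Medication", id = id,
      identifier = identifier_for("Medication", id),
      code = list(coding = list(list(
        system = "http://fhir.de/CodeSystem/bfarm/atc",
        code = sample(pool$drug, 1L)))))
    return(fhir_envelope(id, type, ts,
                         identifier = first_identifier(payload),
                         payload = payload))
  }
  if (length(live_enc) == 0L) stop("no live encounters to reference",
                                   call. = FALSE)
  eid <- sample(live_enc, 1L)
  pid <- sub("-e\\d+$", "", eid)
  # encounters created in this delta are named d-e...; their patient is drawn
  # separately, so re-derive via the live patient pool if the name scheme
  # does not apply
  if (!pid %in% live_pat) pid <- sample(live_pat, 1L)
  subject <- list(reference = paste0("Patient/", pid))
  encounter <- list(reference = paste0("Encounter/", eid))
  if (type == "Condition") {
    id <- mk_id("c")
    payload <- list(
      resourceType = "Condition", id = id,
      identifier = identifier_for("Condition", id),
      code = list(coding = list(list(
        system = "http://fhir.de/CodeSystem/bfarm/icd-10-gm",
        code = sample(pool$condition, 1L)))),
      subject = subject, encounter = encounter, onsetDateTime = when)
  } else if (type == "Observation") {
    id <- mk_id("o")
    payload <- list(
      resourceType = "Observation", id = id,
      identifier = identifier_for("Observation", id),
      code = list(coding = list(list(
        system = "http://loinc.org", code = sample(pool$lab, 1L)))),
      subject = subject, encounter = encounter, effectiveDateTime = when,
      valueQuantity = list(value = round(runif(1, 0.1, 200), 1),
                           unit = "arb.unit"))
  } else if (type == "Procedure") {
    id <- mk_id("pr")
    payload <- list(
      resourceType = "Procedure", id = id,
      identifier = identifier_for("Procedure", id),
      code = list(coding = list(list(
        system = "http://fhir.de/CodeSystem/bfarm/ops",
        code = sample(pool$procedure, 1L)))),
      subject = subject, encounter = encounter, performedDateTime = when)
  } else {
    id <- mk_id(if (type == "MedicationStatement") "ms" else "ma")
    if (length(live_med) == 0L) stop("no live medications to reference",
                                     call. = FALSE)
    payload <- list(
      resourceType = type, id = id,
      identifier = identifier_for(type, id),
      medicationReference = list(
        reference = paste0("Medication/", sample(live_med, 1L))),
      subject = subject, context = encounter, effectiveDateTime = when)
  }
  fhir_envelope(id, type, ts, identifier = first_identifier(payload),
                payload = payload)
}
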