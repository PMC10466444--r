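---
title: "Bulk and incremental FHIR-to-OMOP loading: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bulk and incremental FHIR-to-OMOP loading: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical data warehouses built on the OMOP Common Data Model (CDM) are
typically populated from HL7 FHIR sources by an Extract-Transform-Load
process designed as a *full load*: empty the target, re-read the entire
source, re-write everything. That is fine for a one-off study extract and
hopeless for daily consumers (e.g. trial-recruitment screening lists) where
only a small fraction of the source changes per day. `omopcdc` implements an
ETL engine that supports both modes in one pipeline:

* **Bulk** (`APP_BULKLOAD_ENABLED=true`): truncate the target, process the
  entire source.
* **Incremental** (`APP_BULKLOAD_ENABLED=false`): leave the target alone and
  process only resources created, updated or deleted (CUD) inside a closed
  timestamp window `[DATA_BEGINDATE, DATA_ENDDATE]` — timestamp-based change
  data capture on the source's last-updated metadata (`meta.lastUpdated` for
  FHIR-server sources, `last_updated_at` for gateway-table sources).

The hard part of incremental loading is not reading less; it is *data
correctness under updates and deletions* (no duplicates, no orphans). OMOP
assigns its own surrogate ids and one FHIR resource fans out into several
OMOP tables, so after transformation the link back to the source resource is
lost. The engine therefore tracks, for every standardized row, the identity
of the FHIR resource it came from.

## Identity tracking

A FHIR resource is identified per type by its logical `id` and (optionally)
a business `identifier`. Since ids are only unique per resource type, a
registered 3-letter prefix is prepended (`pat-`, `enc-`, `con-`, `obs-`,
`pro-`, `med-`, `mea-`, `mes-`): the pair (`fhir_logical_id`,
`fhir_identifier`) then identifies a resource database-wide. Two storage
strategies are implemented and must be observationally equivalent:

* **columns** — two extra columns on every standardized table;
* **mapping_tables** — one tracking table per resource type in a separate
  schema, holding `(fhir_logical_id, fhir_identifier, omop_table, omop_id)`.

The per-resource flow is: compute the key → look up all rows carrying it →
delete them → if the source envelope is itself a deletion, stop; otherwise
apply the semantic mapping and insert fresh rows with **new** surrogate ids.
Delete-then-reinsert (rather than in-place update) is what makes
cross-domain mappings safe: an update can move a row to a different table.

Patient and Encounter are the exception: other rows hold `person_id` /
`visit_occurrence_id` foreign keys, so these two types are *upserted in
place* with their surrogate ids preserved. Deleting a Patient or Encounter
cascades to all dependent rows (the engine logs this prominently); the
cascade order is child-first so foreign keys never dangle mid-job.

Rows without a natural surrogate id are handled explicitly:
`fact_relationship` rows (always written as reciprocal pairs) are tracked by
the originating resource's key and addressed internally by rowid under the
mapping-tables strategy; `death` is keyed by `person_id`; `care_site` rows
are shared reference data derived from `Encounter.serviceProvider`, carry an
internal `org-` key, are reused across encounters and are never deleted —
deleting them with "their" encounter would orphan other encounters.

## Semantic mapping

The full MI-I core-data-set mapping is out of scope; the engine ships a
compact deterministic mapping that preserves exactly the structural
properties the incremental logic must survive:

* **multi-table outputs** — Patient → `person` + `observation_period`
  (+ `death` iff deceased); Encounter → `visit_occurrence` (+ `care_site`
  for a new organization, + one `visit_detail` per location entry);
* **cross-domain routing** — coded events land in the table of their code's
  *domain* in the miniature vocabulary (a Condition coded with a
  Procedure-domain code lands in `procedure_occurrence`); unmapped codes are
  never dropped: they land in `observation` with concept id 0;
* **linked rows** — a Condition with a stage/severity code additionally
  emits one stage `observation` row and two reciprocal `fact_relationship`
  rows linking it to the primary row (the spec-level contract mentions only
  the pair; a directed pair needs a concrete second fact, and the stage
  observation is it);
* **reference-dependent mapping** — MedicationAdministration /
  MedicationStatement resolve their drug code *through* the referenced
  Medication resource, whose coded content is cached under its tracking key
  (Medication itself produces no standardized rows).

`observation_period` deserves a note. The design intent is one period per
person spanning min..max of that person's event dates, recomputed on Patient
upsert. Computed naively at mapping time this breaks the headline
equivalence property: a delta that adds events for a patient *without*
re-emitting the patient would widen the span under a full reload but not
under an incremental load. The engine therefore recomputes all observation
periods at the **end of every job** from the final standardized content — a
pure function of end state, identical along both paths. Persons without any
events keep a birth-date placeholder span.

A documented limitation, mirroring the source system's silence on the
matter: dependent resources are re-derived only when they themselves appear
in the CDC window. Updating only a Medication does not rewrite existing
`drug_exposure` rows; the synthetic churn simulator therefore cascades
Medication deletions to their dependents (see below).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `APP_BULKLOAD_ENABLED` | — | `true` = full reload, `false` = incremental |
| `DATA_BEGINDATE`, `DATA_ENDDATE` | — | closed CDC window, UTC, second precision |
| `TRACKING_STRATEGY` | `columns` | identity-tracking storage |
| `max_id` | `2^63 - 1` | per-table surrogate-id ceiling; ids are never reused, so exhaustion is reachable in principle and raises the documented `"id space exhausted"` error (configurable low for testing; the workaround is a bulk reload, which restarts sequences) |

Whether the window bounds are whole days or timestamps is not fixed by the
source material; both are treated as full timestamps and compared in UTC on
a closed interval (both endpoints included, matching the bracket notation of
the configuration contract). Ties among several versions of one resource in
one window are broken by source order, last wins; within a job, resources
are processed in dependency order Patient → Encounter → Medication → rest,
so foreign-key targets always exist before dependents. Each job is one
transaction: a failing envelope rolls the target back to its pre-job state,
which keeps the documented recovery path ("if an incremental load fails, run
a bulk load") safe.

## The synthetic world

There is no public dataset to replay, so the generator *is* the stated
world. Defaults produce a "3-month" (90-day) baseline of roughly 20,000
resources: 550 patients, on average 2 encounters each, per encounter 5
conditions / 7 observations / 2 procedures / 1 medication statement /
1 medication administration (Poisson draws), a pool of 40 shared Medication
resources, 5.7% deceased patients (the death/person ratio of the published
comparison table), 30% staged conditions. Codes are drawn from a packaged
miniature vocabulary (ICD-10-GM-, LOINC-, OPS-, ATC-shaped codes with a few
deliberately cross-domain entries). The daily churn profile defaults to 100
creates / 50 updates / 10 deletes per 10,000 baseline resources of a type —
an explicitly arbitrary, overridable stand-in, since the real per-domain CUD
frequency distribution is not published.

Two generator decisions are load-bearing:

* **Cascaded deletions.** Deleting a Patient/Encounter emits deletion
  envelopes for all dependents, and deleting a Medication for the statements
  and administrations referencing it. Without this the baseline-plus-delta
  collection would not be referentially complete, and a full reload of it
  would (correctly) fail on dangling references while the incremental path
  silently diverged.
* **Observable updates.** Updates flip exactly one payload field (gender,
  encounter class, a code, a value) so that a wrong-row substitution is
  detectable downstream by content, not only by count.

What the generator does **not** emulate: clinical plausibility of values,
profile conformance/validation, multiple identifiers per resource, changing
server endpoints (changing logical ids), and realistic churn volumes. A
green equivalence test therefore establishes that the *mechanism* is
correct under creates, updates, deletions and their cascades — not that any
particular real-world deployment's numbers would be reproduced.

## Evaluation kit

`run_test_design_1()` loads identical data under both tracking strategies
and asserts content equality of the standardized tables (timings are
reported but carry no expectation — the original finding that the column
approach is much faster is an artifact of network-database round trips that
an embedded single-file target does not reproduce). `run_test_design_2()`
asserts the data-correctness hypothesis: for a baseline $B$ and delta $D$,

$$\#\big(\text{bulk}(B) + \text{incremental}(D)\big) \;=\; \#\big(\text{bulk}(B \cup D)\big)$$

for all 13 tables — strengthened here from count equality to content
equality modulo surrogate ids (counts alone cannot detect wrong-row
substitutions). Content comparison replaces every surrogate id and foreign
key by the tracking key of the row (or referenced row) it derives from,
drops always-null housekeeping columns, sorts canonically and compares
multisets per table. The performance hypothesis is checked directionally
only: an incremental load of a ~1.6% delta must be faster than a full
reload on the same machine; no published timing is reproduced.

## Numerical and degenerate-input choices

* Timestamps are stored and compared at second precision in UTC; generator
  timestamps are floored to seconds so that serialization round-trips are
  exact.
* Dates/datetimes are stored as ISO-8601 text in SQLite; lexicographic
  min/max on them is chronological.
* An empty source, an empty CDC window, a deletion of a never-loaded
  resource, and a repeated deletion are all no-ops, not errors.
* Unknown codes map to `(observation, 0)`; unresolvable Medication
  references produce a `drug_exposure` row with concept id 0 plus a warning
  — data is degraded visibly, never dropped silently.
* `source_to_concept_map` is static vocabulary content loaded at
  initialization, outside delete semantics and outside tracking.

## Known limitations

No live FHIR-server/HTTP reads, subscriptions or streaming; no automatic
scheduling of incremental runs; no id reuse after exhaustion (the ceiling is
configurable, the failure is explicit, the workaround is a bulk reload); the
13-table CDM subset only; terminology fidelity is out of scope. Re-deriving
dependent rows when only a referenced resource changes is not supported and
documented above.
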