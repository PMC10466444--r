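test_that("compute_tracking_key applies the registered 3-letter prefixes", {
  med <- fhir_envelope("m1", "Medication", TS0)
  expect_equal(compute_tracking_key(med)$fhir_logical_id, "med-m1")
  expect_equal(compute_tracking_key(med)$fhir_identifier, "")
  mes <- fhir_envelope("s2", "MedicationStatement", TS0,
                       identifier = "sys|A9")
  key <- compute_tracking_key(mes)
  expect_equal(key$fhir_logical_id, "mes-s2")
  expect_equal(key$fhir_identifier, "mes-sys|A9")
  mea <- fhir_envelope("a1", "MedicationAdministration", TS0)
  expect_equal(compute_tracking_key(mea)$fhir_logical_id, "mea-a1")
  # unsupported type: the envelope itself refuses construction, and an
  # envelope-shaped object with a foreign type is refused by the key op
  expect_error(fhir_envelope("d1", "Device", TS0))
  fake <- structure(list(resource_type = "Device", logical_id = "d1",
                         identifier = ""), class = "fhir_envelope")
  expect_error(compute_tracking_key(fake), "Device")
  # prefixes are unique
  expect_equal(anyDuplicated(omopcdc:::FHIR_PREFIXES), 0)
})

test_that("process_envelope: create, update (new ids), delete", {
  db <- fresh_db()
  on.exit(close_db(db))
  run_bulk(bulk_cfg(), envelopes = mini_source(), db = db)
  key <- compute_tracking_key(env_condition("c1", "p1", "e1"))
  old_ids <- lookup_tracking(db, key)

  # new resource: nothing deleted, rows inserted
  new_env <- env_condition("c9", "p1", "e1", "2023-02-01T00:00:00Z")
  rep1 <- process_envelope(new_env, db)
  expect_equal(rep1$counters$rows_deleted, 0)
  expect_gte(rep1$counters$rows_inserted, 1)

  # update: previous rows deleted, fresh rows get NEW ids
  upd <- env_condition("c1", "p1", "e1", "2023-02-01T01:00:00Z",
                       code = "E11.9", stage = "258215001")
  rep2 <- process_envelope(upd, db)
  expect_equal(rep2$counters$rows_deleted, nrow(old_ids))
  new_ids <- lookup_tracking(db, key)
  expect_equal(nrow(new_ids), 4)
  expect_length(intersect(old_ids$omop_id[old_ids$omop_table ==
                                            "condition_occurrence"],
                          new_ids$omop_id[new_ids$omop_table ==
                                            "condition_occurrence"]), 0)

  # deletion: rows removed, nothing inserted, lookup empty afterwards
  rep3 <- process_envelope(env_deleted("c1", "Condition",
                                       "2023-02-01T02:00:00Z"), db)
  expect_equal(rep3$counters$rows_deleted, 4)
  expect_equal(rep3$counters$rows_inserted, 0)
  expect_equal(nrow(lookup_tracking(db, key)), 0)
})

test_that("Patient/Encounter upserts preserve surrogate ids and FKs", {
  for (strategy in c("columns", "mapping_tables")) {
    db <- fresh_db(strategy)
    run_bulk(bulk_cfg(strategy), envelopes = mini_source(), db = db)
    pid_before <- DBI::dbGetQuery(db$con,
      "SELECT person_id, gender_concept_id FROM person
       WHERE person_source_value = 'p1'")
    # gender flip on update; person_id and row count stay put
    upd <- env_patient("p1", "2023-02-01T00:00:00Z", gender = "male")
    rep <- upsert_in_place(upd, db)
    expect_equal(rep$counters$rows_updated, 1)
    pid_after <- DBI::dbGetQuery(db$con,
      "SELECT person_id, gender_concept_id FROM person
       WHERE person_source_value = 'p1'")
    expect_equal(pid_after$person_id, pid_before$person_id)
    expect_equal(pid_before$gender_concept_id, 8532)
    expect_equal(pid_after$gender_concept_id, 8507)
    expect_equal(count_per_table(db)[["person"]], 2L)

    # encounter update: visit_occurrence_id stable, dependents still resolve
    vid_before <- DBI::dbGetQuery(db$con,
      "SELECT visit_occurrence_id FROM visit_occurrence
       WHERE visit_source_value = 'IMP'")$visit_occurrence_id
    upd_e <- env_encounter("e1", "p1", "2023-02-01T01:00:00Z", class = "AMB",
                           n_loc = 2)
    upsert_in_place(upd_e, db)
    after <- DBI::dbGetQuery(db$con,
      "SELECT visit_source_value FROM visit_occurrence
       WHERE visit_occurrence_id = :v", params = list(v = vid_before))
    expect_equal(after$visit_source_value, "AMB")  # same id, new content
    expect_equal(count_per_table(db)[["visit_occurrence"]], 2L)
    expect_true(omopcdc:::check_referential_integrity(db))
    dep <- DBI::dbGetQuery(db$con, paste(
      "SELECT COUNT(*) AS n FROM condition_occurrence c JOIN",
      "visit_occurrence v ON c.visit_occurrence_id = v.visit_occurrence_id"))
    expect_equal(dep$n, 2)

    # upsert of a never-seen Patient is a plain insert
    rep2 <- upsert_in_place(env_patient("p3", "2023-02-01T02:00:00Z"), db)
    expect_equal(rep2$counters$rows_updated, 0)
    expect_equal(count_per_table(db)[["person"]], 3L)
    close_db(db)
  }
})

test_that("upsert_in_place rejects non-upsert resource types", {
  db <- fresh_db()
  on.exit(close_db(db))
  expect_error(upsert_in_place(env_condition("c1", "p1", "e1"), db),
               "Patient and Encounter")
})

test_that("deleted Patient cascades to all dependent rows", {
  db <- fresh_db()
  on.exit(close_db(db))
  run_bulk(bulk_cfg(), envelopes = mini_source(), db = db)
  rep <- process_envelope(env_deleted("p2", "Patient",
                                      "2023-02-01T00:00:00Z"), db)
  expect_gt(rep$counters$rows_deleted, 3)
  counts <- count_per_table(db)
  expect_equal(counts[["person"]], 1L)
  expect_equal(counts[["death"]], 0L)   # p2 was the deceased one
  left <- DBI::dbGetQuery(db$con,
    "SELECT COUNT(*) AS n FROM condition_occurrence")$n
  expect_equal(left, 1)                 # only p1's condition remains
  expect_true(omopcdc:::check_referential_integrity(db))
  # care_site rows are shared reference data and survive the cascade
  expect_equal(counts[["care_site"]], 2L)
})

test_that("deleted Encounter cascades but leaves the person and care site", {
  db <- fresh_db()
  on.exit(close_db(db))
  run_bulk(bulk_cfg(), envelopes = mini_source(), db = db)
  process_envelope(env_deleted("e2", "Encounter", "2023-02-01T00:00:00Z"),
                   db)
  counts <- count_per_table(db)
  expect_equal(counts[["visit_occurrence"]], 1L)
  expect_equal(counts[["person"]], 2L)
  expect_equal(counts[["care_site"]], 2L)
  expect_true(omopcdc:::check_referential_integrity(db))
})

test_that("run_bulk is deterministic and handles the trivial sources", {
  db1 <- fresh_db(); db2 <- fresh_db()
  on.exit(close_db(db1, db2))
  envs <- mini_source()
  r1 <- run_bulk(bulk_cfg(), envelopes = envs, db = db1)
  r2 <- run_bulk(bulk_cfg(), envelopes = envs, db = db2)
  expect_equal(r1$per_table_counts, r2$per_table_counts)
  expect_true(compare_databases(db1, db2)$overall_equal)
  # empty source
  r0 <- run_bulk(bulk_cfg(), envelopes = list(), db = db1)
  expect_equal(unname(r0$per_table_counts[setdiff(
    names(r0$per_table_counts), "source_to_concept_map")]), rep(0L, 12))
  # hand-computed totals for the one-of-each fixture
  r3 <- run_bulk(bulk_cfg(), envelopes = mini_source(), db = db1)
  expect_equal(r3$per_table_counts[["person"]], 2L)
  expect_equal(r3$per_table_counts[["visit_occurrence"]], 2L)
  expect_equal(r3$per_table_counts[["visit_detail"]], 3L)
  expect_equal(r3$per_table_counts[["condition_occurrence"]], 2L)
  expect_equal(r3$per_table_counts[["observation"]], 2L)  # o2 + c1's stage
  expect_equal(r3$per_table_counts[["measurement"]], 1L)
  expect_equal(r3$per_table_counts[["fact_relationship"]], 2L)
  expect_equal(r3$per_table_counts[["drug_exposure"]], 2L)
  expect_equal(r3$per_table_counts[["death"]], 1L)
  expect_equal(r3$per_table_counts[["care_site"]], 2L)
  expect_equal(r3$per_table_counts[["procedure_occurrence"]], 1L)
})

test_that("run_incremental: no-op window, full-history equivalence, idempotence", {
  db <- fresh_db()
  on.exit(close_db(db))
  envs <- mini_source()
  # full history over an empty (initialized) target equals a bulk load
  cfg_all <- incr_cfg("2023-01-01T00:00:00Z", "2023-01-31T00:00:00Z")
  r <- run_incremental(cfg_all, envelopes = envs, db = db)
  db_bulk <- fresh_db()
  run_bulk(bulk_cfg(), envelopes = envs, db = db_bulk)
  expect_equal(r$per_table_counts, count_per_table(db_bulk))
  expect_true(compare_databases(db, db_bulk)$overall_equal)
  close_db(db_bulk)
  # re-running the same window changes nothing
  r2 <- run_incremental(cfg_all, envelopes = envs, db = db)
  expect_equal(r2$per_table_counts, r$per_table_counts)
  # empty window: all counters zero, target untouched
  cfg_none <- incr_cfg("2030-01-01T00:00:00Z", "2030-01-02T00:00:00Z")
  r3 <- run_incremental(cfg_none, envelopes = envs, db = db)
  expect_equal(r3$counters$filtered, 0)
  expect_equal(r3$counters$rows_inserted, 0)
  expect_equal(r3$per_table_counts, r$per_table_counts)
})

test_that("counter invariants hold: filtered <= read, collapsed <= filtered", {
  db <- fresh_db()
  on.exit(close_db(db))
  envs <- c(mini_source(),
            list(env_condition("c1", "p1", "e1", "2023-01-20T00:00:00Z")))
  cfg <- incr_cfg("2023-01-01T00:00:00Z", "2023-01-10T00:00:00Z")
  r <- run_incremental(cfg, envelopes = envs, db = db)
  expect_lte(r$counters$filtered, r$counters$read)
  expect_lte(r$counters$collapsed, r$counters$filtered)
  expect_equal(r$per_table_counts, count_per_table(db))
})

test_that("a failing envelope aborts the whole job transactionally", {
  db <- fresh_db()
  on.exit(close_db(db))
  run_bulk(bulk_cfg(), envelopes = mini_source(), db = db)
  before <- count_per_table(db)
  bad <- list(
    env_condition("cnew", "p1", "e1", "2023-02-01T00:00:00Z"),
    env_condition("cbad", "p1", "ghost", "2023-02-01T01:00:00Z")
  )
  cfg <- incr_cfg("2023-02-01T00:00:00Z", "2023-02-02T00:00:00Z")
  expect_error(run_incremental(cfg, envelopes = bad, db = db),
               "Encounter/ghost")
  # the valid envelope of the failed job must not have leaked in
  expect_equal(count_per_table(db), before)
})

test_that("incremental mode never reduces counts outside its window", {
  db <- fresh_db()
  on.exit(close_db(db))
  run_bulk(bulk_cfg(), envelopes = mini_source(), db = db)
  before <- count_per_table(db)
  # a window only containing a new condition for p1
  delta <- list(env_condition("cwin", "p1", "e1", "2023-03-01T00:00:00Z"))
  cfg <- incr_cfg("2023-03-01T00:00:00Z", "2023-03-02T00:00:00Z")
  run_incremental(cfg, envelopes = delta, db = db)
  after <- count_per_table(db)
  expect_true(all(after >= before))
})

test_that("person_id stays constant across arbitrary update sequences", {
  db <- fresh_db()
  on.exit(close_db(db))
  run_bulk(bulk_cfg(), envelopes = mini_source(), db = db)
  pid0 <- DBI::dbGetQuery(db$con,
    "SELECT person_id FROM person WHERE person_source_value = 'p1'")$person_id
  for (i in 1:5) {
    ts <- sprintf("2023-02-%02dT00:00:00Z", i)
    upsert_in_place(env_patient("p1", ts,
                                gender = c("male", "female")[i %% 2 + 1]),
                    db)
  }
  pid5 <- DBI::dbGetQuery(db$con,
    "SELECT person_id FROM person WHERE person_source_value = 'p1'")$person_id
  expect_equal(pid5, pid0)
  expect_equal(count_per_table(db)[["person"]], 2L)
})

test_that("run_bulk/run_incremental work end-to-end from config + files", {
  src <- withr::local_tempfile(fileext = ".ndjson")
  tgt <- withr::local_tempfile(fileext = ".sqlite")
  write_fixture(mini_source(), "ndjson", src)
  cfg <- load_config(TRUE, source_kind = "ndjson", source_path = src,
                     target_path = tgt)
  r <- run_bulk(cfg)
  expect_equal(r$per_table_counts[["person"]], 2L)
  # incremental over the same file and a covering window is idempotent
  cfg2 <- load_config(FALSE, "2023-01-01T00:00:00Z", "2023-01-31T00:00:00Z",
                      source_kind = "ndjson", source_path = src,
                      target_path = tgt)
  r2 <- run_incremental(cfg2)
  expect_equal(r2$per_table_counts, r$per_table_counts)
  # incremental against a missing target is refused
  cfg3 <- load_config(FALSE, "2023-01-01T00:00:00Z", "2023-01-31T00:00:00Z",
                      source_kind = "ndjson", source_path = src,
                      target_path = tempfile())
  expect_error(run_incremental(cfg3), "not initialized")
})
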