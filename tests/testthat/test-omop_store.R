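test_that("initialize_schema creates the 13 tables under both strategies", {
  db_c <- fresh_db("columns")
  db_m <- fresh_db("mapping_tables")
  on.exit(close_db(db_c, db_m))
  counts <- count_per_table(db_c)
  expect_length(counts, 13)
  expect_equal(unname(counts[setdiff(names(counts),
                                     "source_to_concept_map")]),
               rep(0L, 12))
  # vocabulary is static seed content, loaded at initialize time
  expect_gt(counts[["source_to_concept_map"]], 0)
  # columns strategy: every standardized table carries the tracking columns
  for (tab in names(count_per_table(db_c))) {
    cols <- DBI::dbListFields(db_c$con, tab)
    expect_true(all(c("fhir_logical_id", "fhir_identifier") %in% cols),
                label = paste(tab, "has tracking columns"))
  }
  # mapping strategy: unmodified OMOP tables + 8 per-type tracking tables
  expect_false("fhir_logical_id" %in% DBI::dbListFields(db_m$con, "person"))
  tracking <- grep("^etl_tracking_", DBI::dbListTables(db_m$con),
                   value = TRUE)
  expect_length(tracking, 8)
})

test_that("initialize_schema refuses to clobber an existing target", {
  path <- withr::local_tempfile(fileext = ".sqlite")
  db <- initialize_schema(path)
  omop_close(db)
  expect_error(initialize_schema(path), "already exists")
  db2 <- initialize_schema(path, overwrite = TRUE)
  omop_close(db2)
})

test_that("omop_open recovers strategy and max_id from the file", {
  path <- withr::local_tempfile(fileext = ".sqlite")
  db <- initialize_schema(path, strategy = "mapping_tables", max_id = 99)
  omop_close(db)
  db <- omop_open(path)
  on.exit(omop_close(db))
  expect_equal(db$strategy, "mapping_tables")
  expect_equal(db$max_id, 99)
})

test_that("insert_rows assigns sequential ids and records tracking", {
  for (strategy in c("columns", "mapping_tables")) {
    db <- fresh_db(strategy)
    key <- compute_tracking_key(env_patient("p1"))
    ids <- insert_rows(db, "person",
                       data.frame(gender_concept_id = c(8532L, 8507L),
                                  year_of_birth = c(1950L, 1960L)),
                       key)
    expect_equal(ids, c(1, 2))
    hits <- lookup_tracking(db, key)
    expect_equal(sort(hits$omop_id), c(1, 2))
    expect_equal(unique(hits$omop_table), "person")
    close_db(db)
  }
})

test_that("surrogate ids are strictly increasing and never reused", {
  db <- fresh_db()
  on.exit(close_db(db))
  key <- compute_tracking_key(env_patient("p1"))
  ids1 <- insert_rows(db, "person", data.frame(gender_concept_id = 0L), key)
  n <- delete_by_tracking(db, key)
  expect_equal(n, 1)
  ids2 <- insert_rows(db, "person", data.frame(gender_concept_id = 0L), key)
  expect_gt(ids2, ids1)  # no reuse after deletion
})

test_that("id exhaustion raises the documented error naming the table", {
  db <- fresh_db(max_id = 1)
  on.exit(close_db(db))
  key <- compute_tracking_key(env_patient("p1"))
  expect_error(
    insert_rows(db, "person", data.frame(gender_concept_id = c(0L, 0L)), key),
    "id space exhausted.*person")
})

test_that("foreign-key violations are rejected by the store", {
  db <- fresh_db()
  on.exit(close_db(db))
  key <- compute_tracking_key(env_condition("c1", "p1", "e1"))
  expect_error(insert_rows(db, "condition_occurrence",
                           data.frame(person_id = 4242,
                                      condition_concept_id = 0L),
                           key))
})

test_that("lookup_tracking matches by logical id OR identifier, both strategies", {
  for (strategy in c("columns", "mapping_tables")) {
    db <- fresh_db(strategy)
    e <- env_patient("p1")
    key <- compute_tracking_key(e)
    insert_rows(db, "person", data.frame(gender_concept_id = 0L), key)
    # unknown key -> empty
    miss <- compute_tracking_key(env_patient("nobody"))
    expect_equal(nrow(lookup_tracking(db, miss)), 0)
    # identifier-only match still finds the row
    ident_key <- list(fhir_logical_id = "pat-other",
                      fhir_identifier = key$fhir_identifier)
    expect_equal(nrow(lookup_tracking(db, ident_key)), 1)
    close_db(db)
  }
})

test_that("a multi-table resource is tracked and deleted as a unit", {
  for (strategy in c("columns", "mapping_tables")) {
    db <- fresh_db(strategy)
    envs <- mini_source()
    run_bulk(bulk_cfg(strategy), envelopes = envs, db = db)
    # staged condition c1: primary row + stage observation + 2 fact rows
    key <- compute_tracking_key(env_condition("c1", "p1", "e1"))
    hits <- lookup_tracking(db, key)
    expect_equal(nrow(hits), 4)
    expect_setequal(unique(hits$omop_table),
                    c("condition_occurrence", "observation",
                      "fact_relationship"))
    n <- delete_by_tracking(db, key)
    expect_equal(n, 4)
    expect_equal(nrow(lookup_tracking(db, key)), 0)
    expect_equal(delete_by_tracking(db, key), 0)  # idempotent end state
    close_db(db)
  }
})

test_that("lookup results agree across strategies on the same loaded source", {
  db_c <- fresh_db("columns")
  db_m <- fresh_db("mapping_tables")
  on.exit(close_db(db_c, db_m))
  envs <- mini_source()
  run_bulk(bulk_cfg("columns"), envelopes = envs, db = db_c)
  run_bulk(bulk_cfg("mapping_tables"), envelopes = envs, db = db_m)
  for (e in envs) {
    key <- compute_tracking_key(e)
    a <- lookup_tracking(db_c, key)
    b <- lookup_tracking(db_m, key)
    expect_equal(sort(table(a$omop_table)), sort(table(b$omop_table)),
                 label = paste("hits for", key$fhir_logical_id))
  }
})

test_that("truncate_all empties every table, reseeds vocabulary, resets ids", {
  db <- fresh_db()
  on.exit(close_db(db))
  run_bulk(bulk_cfg(), envelopes = mini_source(), db = db)
  before <- count_per_table(db)
  expect_gt(before[["person"]], 0)
  truncate_all(db)
  after <- count_per_table(db)
  expect_equal(unname(after[setdiff(names(after), "source_to_concept_map")]),
               rep(0L, 12))
  expect_equal(after[["source_to_concept_map"]],
               before[["source_to_concept_map"]])
  # truncating an empty target is a no-op, not an error
  expect_silent(truncate_all(db))
  # reload after truncate reproduces the original counts (and restarts ids)
  run_bulk(bulk_cfg(), envelopes = mini_source(), db = db)
  expect_equal(count_per_table(db), before)
  pid <- DBI::dbGetQuery(db$con, "SELECT MIN(person_id) AS m FROM person")$m
  expect_equal(pid, 1)
})

test_that("count_per_table reflects the person = observation_period pattern", {
  db <- fresh_db()
  on.exit(close_db(db))
  run_bulk(bulk_cfg(), envelopes = list(env_patient("p1")), db = db)
  counts <- count_per_table(db)
  expect_equal(counts[["person"]], 1L)
  expect_equal(counts[["observation_period"]], 1L)
  expect_equal(counts[["death"]], 0L)
})

test_that("standardized content is invariant under the strategy choice", {
  db_c <- fresh_db("columns")
  db_m <- fresh_db("mapping_tables")
  on.exit(close_db(db_c, db_m))
  run_bulk(bulk_cfg("columns"), envelopes = mini_source(), db = db_c)
  run_bulk(bulk_cfg("mapping_tables"), envelopes = mini_source(), db = db_m)
  expect_equal(count_per_table(db_c), count_per_table(db_m))
  rep <- compare_databases(db_c, db_m)
  expect_true(rep$overall_equal)
})
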