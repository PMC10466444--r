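small_cfg <- function(seed = 5) {
  generator_config(n_patients = 40, n_medications = 10, seed = seed)
}

test_that("generate_baseline is deterministic under seed, exact on n_patients", {
  b1 <- generate_baseline(small_cfg())
  b2 <- generate_baseline(small_cfg())
  expect_envelopes_equal(b1, b2)
  types <- vapply(b1, function(e) e$resource_type, "")
  expect_equal(sum(types == "Patient"), 40)
  expect_equal(sum(types == "Medication"), 10)
  # byte-identical serialization
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fixture(b1, "ndjson", f1)
  write_fixture(generate_baseline(small_cfg()), "ndjson", f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed differs
  expect_gt(length(b1), 0)
  b3 <- generate_baseline(small_cfg(seed = 6))
  expect_false(identical(write_fixture(b1, "ndjson", f1) |> readLines(),
                         write_fixture(b3, "ndjson", f2) |> readLines()))
})

test_that("zero patients yield an empty patient stream", {
  b <- generate_baseline(generator_config(n_patients = 0,
                                          n_medications = 0))
  expect_length(b, 0)
})

test_that("baselines are referentially complete with in-span timestamps", {
  cfg <- small_cfg()
  b <- generate_baseline(cfg)
  ids_of <- function(type) {
    vapply(Filter(function(e) e$resource_type == type, b),
           function(e) e$logical_id, "")
  }
  pat <- ids_of("Patient"); enc <- ids_of("Encounter")
  med <- ids_of("Medication")
  unresolved <- vapply(b, function(e) {
    p <- e$payload
    s <- p$subject$reference
    if (!is.null(s) && !sub("Patient/", "", s) %in% pat) return(TRUE)
    for (f in c("encounter", "context")) {
      r <- p[[f]]$reference
      if (!is.null(r) && !sub("Encounter/", "", r) %in% enc) return(TRUE)
    }
    m <- p$medicationReference$reference
    !is.null(m) && !sub("Medication/", "", m) %in% med
  }, logical(1))
  expect_false(any(unresolved))
  ts <- vapply(b, function(e) as.numeric(e$last_updated), numeric(1))
  from <- as.POSIXct("2023-01-01", tz = "UTC")
  expect_true(all(ts >= as.numeric(from)))
  expect_true(all(ts < as.numeric(from + 90 * 86400)))
})

test_that("simulate_day honours exact integer counts and stays in-day", {
  b <- generate_baseline(small_cfg())
  profile <- cud_profile(counts = list(
    Condition = c(created = 3, updated = 5, deleted = 2),
    Observation = c(created = 0, updated = 0, deleted = 0),
    Procedure = c(created = 0, updated = 0, deleted = 0),
    Patient = c(created = 1, updated = 2, deleted = 0),
    Encounter = c(created = 0, updated = 0, deleted = 0),
    Medication = c(created = 0, updated = 0, deleted = 0),
    MedicationStatement = c(created = 0, updated = 0, deleted = 0),
    MedicationAdministration = c(created = 0, updated = 0, deleted = 0)),
    seed = 9)
  day <- as.Date("2023-04-01")
  d <- simulate_day(b, profile, day)
  types <- vapply(d, function(e) e$resource_type, "")
  deleted <- vapply(d, function(e) e$deleted, TRUE)
  base_cond <- vapply(Filter(function(e) e$resource_type == "Condition", b),
                      function(e) e$logical_id, "")
  expect_equal(sum(types == "Condition" & deleted), 2)
  expect_equal(sum(types == "Patient" & !deleted), 3)  # 1 create + 2 updates
  # updates re-emit EXISTING ids, creates mint new ones
  upd_ids <- vapply(Filter(function(e)
    e$resource_type == "Condition" && !e$deleted &&
      !startsWith(e$logical_id, "d-"), d), function(e) e$logical_id, "")
  expect_length(upd_ids, 5)
  expect_true(all(upd_ids %in% base_cond))
  # all timestamps inside the day, after every baseline timestamp
  ts <- vapply(d, function(e) as.numeric(e$last_updated), numeric(1))
  expect_true(all(ts >= as.numeric(as.POSIXct("2023-04-01", tz = "UTC"))))
  expect_true(all(ts < as.numeric(as.POSIXct("2023-04-02", tz = "UTC"))))
  expect_gt(min(ts), max(vapply(b, function(e) as.numeric(e$last_updated),
                                numeric(1))))
  # deterministic under the profile seed
  expect_envelopes_equal(d, simulate_day(b, profile, day))
})

test_that("an all-zero profile yields an empty delta", {
  b <- generate_baseline(small_cfg())
  d <- simulate_day(b, cud_profile(0, 0, 0), as.Date("2023-04-01"))
  expect_length(d, 0)
})

test_that("impossible deletion requests and overlapping days are errors", {
  b <- generate_baseline(generator_config(n_patients = 2,
                                          n_medications = 1))
  profile <- cud_profile(counts = list(
    Patient = c(created = 0, updated = 0, deleted = 5)))
  expect_error(simulate_day(b, profile, as.Date("2023-04-01")),
               "only .* live resources")
  expect_error(simulate_day(b, cud_profile(), as.Date("2023-02-01")),
               "strictly after")
})

test_that("Patient/Encounter/Medication deletions cascade in the delta", {
  b <- generate_baseline(small_cfg())
  profile <- cud_profile(created_rate = 0, updated_rate = 0,
                         counts = list(
                           Patient = c(created = 0, updated = 0, deleted = 2),
                           Medication = c(created = 0, updated = 0,
                                          deleted = 1)),
                         deleted_rate = 0, seed = 3)
  d <- simulate_day(b, profile, as.Date("2023-04-01"))
  expect_true(all(vapply(d, function(e) e$deleted, TRUE)))
  del_ids <- vapply(d, function(e) e$logical_id, "")
  # every baseline resource referencing a deleted id is itself deleted
  orphaned <- vapply(b, function(e) {
    refs <- c(e$payload$subject$reference, e$payload$encounter$reference,
              e$payload$context$reference,
              e$payload$medicationReference$reference)
    refs <- sub("^[^/]*/", "", refs)
    any(refs %in% del_ids) && !e$logical_id %in% del_ids
  }, logical(1))
  expect_false(any(orphaned))
})

test_that("fixtures round-trip through both dialects from the generator", {
  b <- generate_baseline(generator_config(n_patients = 5,
                                          n_medications = 3))
  nd <- withr::local_tempfile(fileext = ".ndjson")
  gw <- withr::local_tempfile(fileext = ".csv")
  write_fixture(b, "ndjson", nd)
  write_fixture(b, "gateway_table", gw)
  expect_envelopes_equal(read_ndjson(nd), b)
  expect_envelopes_equal(read_gateway_table(gw), b)
})
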