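test_that("read_ndjson maps lines to envelopes and validates metadata", {
  path <- withr::local_tempfile(fileext = ".ndjson")
  writeLines(c(
    '{"resourceType":"Patient","id":"p1","meta":{"lastUpdated":"2023-01-02T08:00:00Z"},"gender":"female","identifier":[{"system":"sys","value":"A1"}]}',
    '{"resourceType":"Condition","id":"c9","meta":{"lastUpdated":"2023-01-02T10:00:00Z","tag":[{"code":"DELETED"}]}}'
  ), path)
  envs <- read_ndjson(path)
  expect_length(envs, 2)
  expect_equal(envs[[1]]$logical_id, "p1")
  expect_equal(envs[[1]]$resource_type, "Patient")
  expect_false(envs[[1]]$deleted)
  expect_equal(envs[[1]]$identifier, "sys|A1")
  expect_equal(format(envs[[1]]$last_updated, "%H:%M", tz = "UTC"), "08:00")
  expect_true(envs[[2]]$deleted)
  expect_length(envs[[2]]$payload, 0)
})

test_that("read_ndjson on an empty file yields an empty collection", {
  path <- withr::local_tempfile(fileext = ".ndjson")
  file.create(path)
  expect_length(read_ndjson(path), 0)
})

test_that("read_ndjson errors name the offending line", {
  path <- withr::local_tempfile(fileext = ".ndjson")
  ok <- '{"resourceType":"Patient","id":"pX","meta":{"lastUpdated":"2023-01-02T08:00:00Z"}}'
  writeLines(c(ok, ok, ok,
               '{"resourceType":"Patient","meta":{"lastUpdated":"2023-01-02T08:00:00Z"}}'),
             path)
  expect_error(read_ndjson(path), "line 4")
  writeLines(c(ok, "{not json"), path)
  expect_error(read_ndjson(path), "line 2")
  writeLines('{"resourceType":"Patient","id":"p1"}', path)
  expect_error(read_ndjson(path), "meta.lastUpdated")
})

test_that("read_gateway_table parses rows and flags deletions", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "fhir_id,type,data,last_updated_at,is_deleted",
    'c9,Condition,,2023-01-02T10:00:00Z,true',
    'c9,Condition,"{""resourceType"":""Condition"",""id"":""c9""}",2023-01-01T10:00:00Z,false'
  ), path)
  envs <- read_gateway_table(path)
  expect_length(envs, 2)  # versions survive; collapsing happens later
  expect_true(envs[[1]]$deleted)
  expect_false(envs[[2]]$deleted)
  expect_equal(envs[[2]]$payload$id, "c9")
})

test_that("read_gateway_table errors name a missing column", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("fhir_id,type,data,is_deleted", "x,Patient,,false"), path)
  expect_error(read_gateway_table(path), "missing column last_updated_at")
})

test_that("filter_window is a closed interval on both endpoints", {
  mk <- function(ts) env_condition("c1", "p1", "e1", ts)
  cfg <- incr_cfg("2023-02-01T00:00:00Z", "2023-02-02T00:00:00Z")
  at_begin <- mk("2023-02-01T00:00:00Z")
  at_end <- mk("2023-02-02T00:00:00Z")
  before <- mk("2023-01-31T23:59:59Z")
  after <- mk("2023-02-02T00:00:01Z")
  out <- filter_window(list(before, at_begin, at_end, after), cfg)
  expect_length(out, 2)
  expect_equal(vapply(out, function(e) format(e$last_updated, "%d", tz = "UTC"),
                      ""), c("01", "02"))
})

test_that("filter_window identity limit and idempotence", {
  envs <- mini_source()
  ts <- vapply(envs, function(e) as.numeric(e$last_updated), numeric(1))
  cfg <- incr_cfg(as.POSIXct(min(ts), origin = "1970-01-01", tz = "UTC"),
                  as.POSIXct(max(ts), origin = "1970-01-01", tz = "UTC"))
  once <- filter_window(envs, cfg)
  expect_identical(once, envs)             # window covering min..max
  expect_identical(filter_window(once, cfg), once)  # idempotent
  # empty result is legal
  cfg_empty <- incr_cfg("2030-01-01T00:00:00Z", "2030-01-02T00:00:00Z")
  expect_length(filter_window(envs, cfg_empty), 0)
})

test_that("filter_window refuses bulk configs", {
  expect_error(filter_window(mini_source(), bulk_cfg()), "incremental")
})

test_that("collapse_versions keeps the max-timestamp version under all orderings", {
  v1 <- env_condition("c1", "p1", "e1", "2023-01-05T08:00:00Z")
  v2 <- env_condition("c1", "p1", "e1", "2023-01-06T08:00:00Z",
                      code = "E11.9")
  v3 <- env_deleted("c1", "Condition", "2023-01-07T08:00:00Z")
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  for (p in perms) {
    input <- list(v1, v2, v3)[p]
    got <- collapse_versions(input)
    want <- collapse_oracle(input)
    expect_length(got, 1)
    expect_true(got[[1]]$deleted)          # max timestamp is the deletion
    expect_envelopes_equal(got, want)
  }
})

test_that("collapse_versions: distinct ids pass through, ties go to source order", {
  envs <- mini_source()
  expect_identical(collapse_versions(envs), envs)
  # identical timestamps: later source element wins
  a <- env_condition("c1", "p1", "e1", "2023-01-05T08:00:00Z")
  b <- env_condition("c1", "p1", "e1", "2023-01-05T08:00:00Z",
                     code = "E11.9")
  got <- collapse_versions(list(a, b))
  expect_length(got, 1)
  expect_equal(got[[1]]$payload$code$coding[[1]]$code, "E11.9")
})

test_that("collapse_versions output size equals distinct (type, id) pairs", {
  set.seed(42)
  for (rep in 1:5) {
    ids <- sample(c("x1", "x2", "x3"), 8, replace = TRUE)
    types <- sample(c("Condition", "Observation"), 8, replace = TRUE)
    envs <- lapply(seq_along(ids), function(i) {
      fhir_envelope(ids[i], types[i],
                    as.POSIXct("2023-01-01", tz = "UTC") +
                      sample.int(1000, 1),
                    payload = list(resourceType = types[i], id = ids[i]))
    })
    got <- collapse_versions(envs)
    expect_length(got, nrow(unique(data.frame(ids, types))))
    expect_envelopes_equal(got, collapse_oracle(envs))
  }
})

test_that("both source dialects round-trip to equal envelope collections", {
  envs <- c(mini_source(),
            list(env_deleted("gone1", "Condition", "2023-01-06T00:00:00Z")))
  nd <- withr::local_tempfile(fileext = ".ndjson")
  gw <- withr::local_tempfile(fileext = ".csv")
  write_fixture(envs, "ndjson", nd)
  write_fixture(envs, "gateway_table", gw)
  from_nd <- read_ndjson(nd)
  from_gw <- read_gateway_table(gw)
  expect_envelopes_equal(from_nd, envs)
  expect_envelopes_equal(from_gw, envs)
  expect_envelopes_equal(from_nd, from_gw)  # dialect equivalence
  expect_error(write_fixture(envs, "parquet", nd))
})

test_that("load_config validates the CDC window and mode", {
  expect_error(load_config(FALSE), "DATA_BEGINDATE")
  expect_error(load_config(FALSE, "2023-01-02T00:00:00Z",
                           "2023-01-01T00:00:00Z"), "must not be after")
  cfg <- load_config(TRUE)  # bulk ignores the window
  expect_true(cfg$bulkload_enabled)
})

test_that("configuration files round-trip through the printed key names", {
  cfg <- load_config(FALSE, "2023-04-01T00:00:00Z", "2023-04-01T23:59:59Z",
                     tracking_strategy = "mapping_tables",
                     source_kind = "gateway_table",
                     source_path = "src.csv", target_path = "t.sqlite")
  path <- withr::local_tempfile(fileext = ".conf")
  write_etl_config(cfg, path)
  txt <- readLines(path)
  expect_true(any(grepl("^APP_BULKLOAD_ENABLED=false$", txt)))
  expect_true(any(grepl("^DATA_BEGINDATE=2023-04-01T00:00:00Z$", txt)))
  expect_true(any(grepl("^DATA_ENDDATE=", txt)))
  back <- read_etl_config(path)
  expect_equal(back$bulkload_enabled, FALSE)
  expect_equal(back$tracking_strategy, "mapping_tables")
  expect_equal(as.numeric(back$data_begindate), as.numeric(cfg$data_begindate))
})
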