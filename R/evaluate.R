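# Evaluation kit: the two ETL test designs. Design 1 compares the two
# identity-tracking strategies (columns vs mapping tables) for content
# equality and relative runtime; design 2 verifies the data-correctness
# hypothesis that a full reload over baseline-plus-delta equals an initial
# full load followed by an incremental load of the delta, for all 13 tables,
# by count AND by content modulo surrogate ids.

# Surrogate/housekeeping columns projected away before content comparison.
NOISE_COLS <- c("provider_id", "location_id", "preceding_visit_occurrence_id",
                "preceding_visit_detail_id", "visit_detail_parent_id",
                "visit_detail_id", "fhir_logical_id", "fhir_identifier")

# Canonical content of a target database: surrogate ids are replaced by the
# tracking key of the originating resource (strategy-appropriate lookup), and
# foreign keys by the referenced row's key (person -> "pat-...", visit ->
# "enc-...", care_site -> its source value), then rows are sorted on all
# remaining columns. Two loads of the same final source state canonicalize to
# identical tables regardless of the ids they assigned.
canonical_tables <- function(db) {
  con <- db$con
  keymaps <- list()
  for (tab in setdiff(names(OMOP_TABLES),
                      c("source_to_concept_map", "fact_relationship"))) {
    idexpr <- surrogate_expr(tab)
    if (db$strategy == "columns") {
      km <- DBI::dbGetQuery(con, sprintf(
        "SELECT %s AS id, fhir_logical_id AS key FROM %s", idexpr, tab))
    } else {
      parts <- vapply(FHIR_TYPES, function(rt) sprintf(
        "SELECT omop_id AS id, fhir_logical_id AS key FROM %s WHERE omop_table = '%s'",
        tracking_table_name(rt), tab), character(1))
      km <- DBI::dbGetQuery(con, paste(parts, collapse = " UNION ALL "))
      if (tab == "care_site") {
        km <- DBI::dbGetQuery(con, paste(
          "SELECT care_site_id AS id,",
          "'org-' || care_site_source_value AS key FROM care_site"))
      }
    }
    keymaps[[tab]] <- setNames(km$key, format(km$id, scientific = FALSE,
                                              trim = TRUE))
  }
  lookup <- function(tab, ids) {
    out <- unname(keymaps[[tab]][format(as.numeric(ids), scientific = FALSE,
                                        trim = TRUE)])
    out[is.na(ids)] <- NA_character_
    out
  }
  out <- list()
  for (tab in names(OMOP_TABLES)) {
    x <- data.table::as.data.table(
      DBI::dbGetQuery(con, paste0("SELECT * FROM ", tab)))
    if (tab != "source_to_concept_map" && tab != "fact_relationship" &&
        nrow(x) > 0) {
      x$row_key <- lookup(tab, x[[surrogate_expr(tab)]])
    } else if (nrow(x) == 0 && tab != "source_to_concept_map" &&
               tab != "fact_relationship") {
      x$row_key <- character(0)
    }
    if (tab == "fact_relationship" && nrow(x) > 0) {
      t1 <- names(DOMAIN_CONCEPT_ID)[match(x$domain_concept_id_1,
                                           DOMAIN_CONCEPT_ID)]
      t2 <- names(DOMAIN_CONCEPT_ID)[match(x$domain_concept_id_2,
                                           DOMAIN_CONCEPT_ID)]
      x$fact_key_1 <- vapply(seq_len(nrow(x)), function(i)
        lookup(t1[i], x$fact_id_1[i]), character(1))
      x$fact_key_2 <- vapply(seq_len(nrow(x)), function(i)
        lookup(t2[i], x$fact_id_2[i]), character(1))
      x$fact_id_1 <- NULL; x$fact_id_2 <- NULL
    } else if (tab == "fact_relationship") {
      x$fact_key_1 <- character(0); x$fact_key_2 <- character(0)
      x$fact_id_1 <- NULL; x$fact_id_2 <- NULL
    }
    drop <- intersect(c(NOISE_COLS, unname(SURROGATE_ID[tab])), names(x))
    if (length(drop)) x[, (drop) := NULL]
    for (col in intersect(c("person_id", "visit_occurrence_id"), names(x))) {
      parent <- if (col == "person_id") "person" else "visit_occurrence"
      data.table::set(x, j = col, value = lookup(parent, x[[col]]))
    }
    if ("care_site_id" %in% names(x)) {
      data.table::set(x, j = "care_site_id",
                      value = lookup("care_site", x[["care_site_id"]]))
    }
    for (col in names(x)) {
      if (is.numeric(x[[col]])) data.table::set(x, j = col,
                                                value = as.numeric(x[[col]]))
    }
    data.table::setcolorder(x, sort(names(x)))
    data.table::setorderv(x, names(x), na.last = TRUE)
    out[[tab]] <- x
  }
  out
}

#' Compare two OMOP target databases
#'
#' Count comparison is raw per-table row counts; content comparison projects
#' away surrogate ids and tracking columns, rewrites foreign keys to the
#' tracking keys of the referenced rows, canonically sorts, and tests
#' multiset equality per table. The verdicts are symmetric in the two
#' arguments.
#'
#' @param db_a,db_b Two `omop_db` handles (any tracking strategies).
#' @return A `comparison_report`: per-table counts and equality flags plus
#'   `overall_equal` (conjunction of all per-table content verdicts).
#' @export
compare_databases <- function(db_a, db_b) {
  counts_a <- count_per_table(db_a)
  counts_b <- count_per_table(db_b)
  can_a <- canonical_tables(db_a)
  can_b <- canonical_tables(db_b)
  per_table <- lapply(setNames(nm = sort(names(OMOP_TABLES))), function(tab) {
    content_equal <- isTRUE(all.equal(as.data.frame(can_a[[tab]]),
                                      as.data.frame(can_b[[tab]]),
                                      check.attributes = FALSE)) &&
      nrow(can_a[[tab]]) == nrow(can_b[[tab]])
    list(count_a = unname(counts_a[tab]), count_b = unname(counts_b[tab]),
         equal = unname(counts_a[tab] == counts_b[tab]),
         content_equal = content_equal)
  })
  structure(
    list(per_table = per_table,
         overall_equal = all(vapply(per_table, `[[`, TRUE, "content_equal")),
         timings = NULL),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  cat(sprintf("  %-24s %10s %10s %6s %8s\n", "table", "count_a", "count_b",
              "equal", "content"))
  for (tab in names(x$per_table)) {
    p <- x$per_table[[tab]]
    cat(sprintf("  %-24s %10d %10d %6s %8s\n", tab, p$count_a, p$count_b,
                p$equal, p$content_equal))
  }
  cat("  overall_equal:", x$overall_equal, "\n")
  if (!is.null(x$timings)) {
    for (k in names(x$timings)) {
      cat(sprintf("  t(%s) = %.2f s\n", k, x$timings[[k]]))
    }
  }
  invisible(x)
}

#' ETL test design 2: bulk-vs-incremental data correctness
#'
#' Builds a baseline B (the "3-month" span of the generator config) and a
#' one-day delta D, then executes path A = bulk(B and D together) and path
#' B = bulk(B) followed by incremental(D) into two fresh targets, and
#' compares all 13 tables by count and content modulo surrogate ids. Wall
#' clock timings of the three loads are recorded for the directional
#' performance hypothesis (an incremental load of a small delta should beat a
#' full reload); absolute timings carry no expectation.
#'
#' @param gen_config A [generator_config].
#' @param profile A [cud_profile].
#' @param seed Integer; reseeds generator and simulator.
#' @param strategy Tracking strategy for both targets.
#' @return A `comparison_report` with `timings` (seconds) for `bulk_full`
#'   (B and D), `bulk_initial` (B) and `incremental` (D).
#' @export
run_test_design_2 <- function(gen_config = generator_config(),
                              profile = cud_profile(),
                              seed = NULL,
                              strategy = "columns") {
  if (!is.null(seed)) {
    gen_config$seed <- as.integer(seed)
    profile$seed <- as.integer(seed) + 1L
  }
  vocab <- read_vocabulary()
  baseline <- generate_baseline(gen_config, vocab)
  day <- gen_config$base_date + gen_config$span_days
  delta <- simulate_day(baseline, profile, day, vocab)
  window <- c(as.POSIXct(paste(day, "00:00:00"), tz = "UTC"),
              as.POSIXct(paste(day, "23:59:59"), tz = "UTC"))

  db_a <- initialize_schema(tempfile(fileext = ".sqlite"),
                            strategy = strategy, vocabulary = vocab)
  db_b <- initialize_schema(tempfile(fileext = ".sqlite"),
                            strategy = strategy, vocabulary = vocab)
  on.exit({
    path_a <- db_a$path; path_b <- db_b$path
    omop_close(db_a); omop_close(db_b)
    unlink(c(path_a, path_b))
  })
  cfg_bulk <- load_config(TRUE, tracking_strategy = strategy)
  cfg_incr <- load_config(FALSE, window[1], window[2],
                          tracking_strategy = strategy)
  t_full <- system.time(
    run_bulk(cfg_bulk, envelopes = c(baseline, delta), db = db_a))["elapsed"]
  t_init <- system.time(
    run_bulk(cfg_bulk, envelopes = baseline, db = db_b))["elapsed"]
  t_incr <- system.time(
    run_incremental(cfg_incr, envelopes = delta, db = db_b))["elapsed"]

  report <- compare_databases(db_a, db_b)
  report$timings <- list(bulk_full = unname(t_full),
                         bulk_initial = unname(t_init),
                         incremental = unname(t_incr))
  report
}

#' ETL test design 1: tracking-strategy comparison
#'
#' Runs the identical bulk-then-incremental load sequence under both tracking
#' strategies (extra columns vs mapping tables), asserts content equality of
#' the standardized tables and reports the relative timings. No absolute
#' runtime expectation is attached: the verdict is the content equality, the
#' ratio is informational.
#'
#' @inheritParams run_test_design_2
#' @return A `comparison_report` (`count_a`/`content` columns refer to
#'   columns-strategy vs mapping-tables-strategy targets) whose `timings`
#'   hold per-strategy totals and their ratio.
#' @export
run_test_design_1 <- function(gen_config = generator_config(),
                              profile = cud_profile(),
                              seed = NULL) {
  if (!is.null(seed)) {
    gen_config$seed <- as.integer(seed)
    profile$seed <- as.integer(seed) + 1L
  }
  vocab <- read_vocabulary()
  baseline <- generate_baseline(gen_config, vocab)
  day <- gen_config$base_date + gen_config$span_days
  delta <- simulate_day(baseline, profile, day, vocab)
  window <- c(as.POSIXct(paste(day, "00:00:00"), tz = "UTC"),
              as.POSIXct(paste(day, "23:59:59"), tz = "UTC"))
  timings <- list()
  dbs <- list()
  for (strategy in c("columns", "mapping_tables")) {
    db <- initialize_schema(tempfile(fileext = ".sqlite"),
                            strategy = strategy, vocabulary = vocab)
    cfg_bulk <- load_config(TRUE, tracking_strategy = strategy)
    cfg_incr <- load_config(FALSE, window[1], window[2],
                            tracking_strategy = strategy)
    t <- system.time({
      run_bulk(cfg_bulk, envelopes = baseline, db = db)
      run_incremental(cfg_incr, envelopes = delta, db = db)
    })["elapsed"]
    timings[[strategy]] <- unname(t)
    dbs[[strategy]] <- db
  }
  on.exit({
    for (db in dbs) {
      path <- db$path
      omop_close(db)
      unlink(path)
    }
  })
  report <- compare_databases(dbs$columns, dbs$mapping_tables)
  timings$ratio_mapping_over_columns <-
    timings$mapping_tables / max(timings$columns, 1e-9)
  report$timings <- timings
  report
}
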