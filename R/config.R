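#' ETL load configuration
#'
#' Bundles the switches that select between a bulk (full reload) and an
#' incremental (timestamp CDC) run, mirroring the configuration file of the
#' ETL process: `APP_BULKLOAD_ENABLED` selects the mode (`TRUE` = bulk,
#' `FALSE` = incremental) and `DATA_BEGINDATE` / `DATA_ENDDATE` bound the
#' closed CDC window for incremental runs. The window parameters are ignored
#' when bulk loading is enabled.
#'
#' @param bulkload_enabled Logical; `TRUE` runs a full reload (target emptied
#'   first), `FALSE` an incremental load over the CDC window.
#' @param data_begindate,data_enddate Window bounds (ISO-8601 character or
#'   `POSIXct`, normalized to UTC). Required when `bulkload_enabled = FALSE`;
#'   must satisfy `data_begindate <= data_enddate`.
#' @param tracking_strategy `"columns"` (two extra tracking columns on every
#'   standardized table) or `"mapping_tables"` (per-resource-type tracking
#'   tables in a separate schema).
#' @param source_kind `"ndjson"` (FHIR-server style, `meta.lastUpdated`) or
#'   `"gateway_table"` (FHIR-gateway style CSV with `last_updated_at`).
#' @param source_path Path to the source file.
#' @param target_path Path to the target SQLite database file.
#' @return An object of class `load_config`.
#' @export
load_config <- function(bulkload_enabled,
                        data_begindate = NULL, data_enddate = NULL,
                        tracking_strategy = c("columns", "mapping_tables"),
                        source_kind = c("ndjson", "gateway_table"),
                        source_path = "", target_path = "") {
  stopifnot(is.logical(bulkload_enabled), length(bulkload_enabled) == 1L,
            !is.na(bulkload_enabled))
  tracking_strategy <- match.arg(tracking_strategy)
  source_kind <- match.arg(source_kind)
  if (!bulkload_enabled) {
    if (is.null(data_begindate) || is.null(data_enddate)) {
      stop("incremental load requires DATA_BEGINDATE and DATA_ENDDATE",
           call. = FALSE)
    }
    data_begindate <- as_utc(data_begindate)
    data_enddate <- as_utc(data_enddate)
    if (data_begindate > data_enddate) {
      stop("DATA_BEGINDATE must not be after DATA_ENDDATE", call. = FALSE)
    }
  } else {
    # bulk ignores the window
    if (!is.null(data_begindate)) data_begindate <- as_utc(data_begindate)
    if (!is.null(data_enddate)) data_enddate <- as_utc(data_enddate)
  }
  structure(
    list(
      bulkload_enabled = bulkload_enabled,
      data_begindate = data_begindate,
      data_enddate = data_enddate,
      tracking_strategy = tracking_strategy,
      source_kind = source_kind,
      source_path = source_path,
      target_path = target_path
    ),
    class = "load_config"
  )
}

#' @export
print.load_config <- function(x, ...) {
  cat("<load_config>\n")
  cat("  APP_BULKLOAD_ENABLED:", tolower(x$bulkload_enabled), "\n")
  if (!is.null(x$data_begindate))
    cat("  DATA_BEGINDATE:      ", fmt_utc(x$data_begindate), "\n")
  if (!is.null(x$data_enddate))
    cat("  DATA_ENDDATE:        ", fmt_utc(x$data_enddate), "\n")
  cat("  TRACKING_STRATEGY:   ", x$tracking_strategy, "\n")
  cat("  SOURCE:              ", x$source_kind, x$source_path, "\n")
  cat("  TARGET:              ", x$target_path, "\n")
  invisible(x)
}

#' Read an ETL configuration file
#'
#' Parses a `key=value` configuration file with the keys
#' `APP_BULKLOAD_ENABLED`, `DATA_BEGINDATE`, `DATA_ENDDATE`,
#' `TRACKING_STRATEGY`, `SOURCE_KIND`, `SOURCE_PATH` and `TARGET_PATH`.
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path Path to the configuration file.
#' @return A [load_config].
#' @export
read_etl_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]],
                     call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  get <- function(k, default = NULL) {
    i <- match(k, keys)
    if (is.na(i)) default else vals[i]
  }
  bulk <- get("APP_BULKLOAD_ENABLED")
  if (is.null(bulk)) stop("config is missing APP_BULKLOAD_ENABLED",
                          call. = FALSE)
  load_config(
    bulkload_enabled = tolower(bulk) == "true",
    data_begindate = get("DATA_BEGINDATE"),
    data_enddate = get("DATA_ENDDATE"),
    tracking_strategy = get("TRACKING_STRATEGY", "columns"),
    source_kind = get("SOURCE_KIND", "ndjson"),
    source_path = get("SOURCE_PATH", ""),
    target_path = get("TARGET_PATH", "")
  )
}

#' Write an ETL configuration file
#'
#' Inverse of [read_etl_config()].
#'
#' @param config A [load_config].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_etl_config <- function(config, path) {
  stopifnot(inherits(config, "load_config"))
  lines <- c(
    paste0("APP_BULKLOAD_ENABLED=", tolower(config$bulkload_enabled)),
    if (!is.null(config$data_begindate))
      paste0("DATA_BEGINDATE=", fmt_utc(config$data_begindate)),
    if (!is.null(config$data_enddate))
      paste0("DATA_ENDDATE=", fmt_utc(config$data_enddate)),
    paste0("TRACKING_STRATEGY=", config$tracking_strategy),
    paste0("SOURCE_KIND=", config$source_kind),
    paste0("SOURCE_PATH=", config$source_path),
    paste0("TARGET_PATH=", config$target_path)
  )
  writeLines(lines, path)
  invisible(path)
}
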