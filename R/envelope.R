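#' Construct a FHIR source envelope
#'
#' An envelope is the uniform in-memory representation of one FHIR R4 resource
#' version as read from either source dialect (NDJSON file or FHIR-gateway
#' table): the logical id, the resource type, the first business identifier
#' (as `"system|value"`), the structured payload, the last-updated timestamp
#' and a deletion flag. Deleted envelopes may carry an empty payload.
#'
#' @param logical_id Non-empty character scalar, the FHIR `id` (unique per
#'   resource type on one server).
#' @param resource_type One of the supported FHIR resource types (Patient,
#'   Encounter, Condition, Observation, Procedure, Medication,
#'   MedicationAdministration, MedicationStatement).
#' @param last_updated `POSIXct` (or ISO-8601 character) timestamp; always
#'   present in both source dialects (`meta.lastUpdated` / `last_updated_at`).
#'   Normalized to UTC.
#' @param payload Named list with the resource content; may be empty for
#'   deleted envelopes.
#' @param identifier Character scalar `"system|value"` of the first business
#'   identifier, or `""` when the resource has none.
#' @param deleted Logical scalar; `TRUE` marks a source-side deletion.
#' @return An object of class `fhir_envelope`.
#' @examples
#' fhir_envelope("p1", "Patient", "2023-01-02T08:00:00Z",
#'               payload = list(gender = "female"))
#' @export
fhir_envelope <- function(logical_id, resource_type, last_updated,
                          payload = list(), identifier = "",
                          deleted = FALSE) {
  if (!is.character(logical_id) || length(logical_id) != 1L ||
      is.na(logical_id) || !nzchar(logical_id)) {
    stop("logical_id must be a non-empty character scalar", call. = FALSE)
  }
  resource_type <- match.arg(resource_type, FHIR_TYPES)
  last_updated <- as_utc(last_updated)
  if (length(last_updated) != 1L || is.na(last_updated)) {
    stop("last_updated must be a single valid timestamp", call. = FALSE)
  }
  if (is.null(identifier) || is.na(identifier)) identifier <- ""
  structure(
    list(
      logical_id = logical_id,
      resource_type = resource_type,
      identifier = as.character(identifier),
      payload = payload,
      last_updated = last_updated,
      deleted = isTRUE(deleted)
    ),
    class = "fhir_envelope"
  )
}

#' @export
print.fhir_envelope <- function(x, ...) {
  cat(sprintf(
    "<fhir_envelope> %s/%s %s%s\n", x$resource_type, x$logical_id,
    format(x$last_updated, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    if (x$deleted) " [deleted]" else ""
  ))
  invisible(x)
}

# Parse ISO-8601 / POSIXct to POSIXct UTC.
as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"  # POSIXct is absolute; only the label moves
    return(x)
  }
  x <- as.character(x)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                   "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))
  out
}

fmt_utc <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

envelope_field <- function(envelopes, field, mode = "character") {
  if (mode == "numeric") {
    vapply(envelopes, function(e) as.numeric(e[[field]]), numeric(1))
  } else if (mode == "logical") {
    vapply(envelopes, function(e) isTRUE(e[[field]]), logical(1))
  } else {
    vapply(envelopes, function(e) as.character(e[[field]]), character(1))
  }
}

#' Filter envelopes to a change-data-capture window
#'
#' Timestamp-based change data capture: keeps exactly the envelopes whose
#' last-updated timestamp lies in the closed interval
#' `[DATA_BEGINDATE, DATA_ENDDATE]` of an incremental-load configuration.
#' Both endpoints are inclusive and all comparisons are made in UTC. The
#' original order is preserved; an empty result is legal.
#'
#' @param envelopes List of [fhir_envelope] objects.
#' @param config A [load_config] with `bulkload_enabled = FALSE`.
#' @return The filtered list of envelopes.
#' @export
filter_window <- function(envelopes, config) {
  stopifnot(inherits(config, "load_config"))
  if (isTRUE(config$bulkload_enabled)) {
    stop("filter_window applies to incremental loads only ",
         "(bulkload_enabled must be FALSE)", call. = FALSE)
  }
  if (length(envelopes) == 0L) return(envelopes)
  ts <- envelope_field(envelopes, "last_updated", "numeric")
  keep <- ts >= as.numeric(config$data_begindate) &
    ts <= as.numeric(config$data_enddate)
  envelopes[keep]
}

#' Collapse multiple versions of a resource to its final state
#'
#' A CDC window (or a concatenation of a baseline and a delta) may contain
#' several versions of one resource. Only the final state matters for the
#' delete-then-reinsert semantics, so per `(resource_type, logical_id)` only
#' the envelope with the greatest last-updated timestamp survives; ties are
#' broken by source order with the later element winning. Relative order of
#' the surviving envelopes follows their position in the input.
#'
#' @param envelopes List of [fhir_envelope] objects.
#' @return List of envelopes with one entry per `(resource_type, logical_id)`.
#' @export
collapse_versions <- function(envelopes) {
  if (length(envelopes) <= 1L) return(envelopes)
  key <- paste(envelope_field(envelopes, "resource_type"),
               envelope_field(envelopes, "logical_id"), sep = "\r")
  ts <- envelope_field(envelopes, "last_updated", "numeric")
  # stable: for equal timestamps within a key the later source index wins
  best <- integer(0)
  idx <- split(seq_along(envelopes), key)
  best <- vapply(idx, function(i) {
    t_i <- ts[i]
    i[max(which(t_i == max(t_i)))]
  }, integer(1))
  envelopes[sort(unname(best))]
}
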