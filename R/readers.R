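#' Read FHIR resources from an NDJSON file
#'
#' FHIR-server style source dialect: one FHIR R4 resource per line, UTF-8.
#' Each resource must carry `resourceType`, `id` and `meta.lastUpdated`.
#' Deletions are marked by a `meta.tag` entry with code `"DELETED"` (deleted
#' resources may otherwise be payload-empty). The first entry of the
#' resource's `identifier` list is extracted as `"system|value"`; resources
#' without an identifier get an empty one.
#'
#' @param path Path to an NDJSON file.
#' @return List of [fhir_envelope] objects, one per line, in file order.
#' @export
read_ndjson <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    res <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) {
        stop(sprintf("malformed NDJSON at line %d: %s",
                     i, conditionMessage(e)), call. = FALSE)
      }
    )
    out[[i]] <- resource_to_envelope(res, where = sprintf("line %d", i))
  }
  out
}

# Convert one parsed FHIR resource (named list) into an envelope.
resource_to_envelope <- function(res, where = "resource") {
  rt <- res[["resourceType"]]
  if (is.null(rt)) stop("missing resourceType at ", where, call. = FALSE)
  id <- res[["id"]]
  if (is.null(id) || !nzchar(id)) {
    stop(sprintf("missing id in %s resource at %s", rt, where), call. = FALSE)
  }
  lu <- res[["meta"]][["lastUpdated"]]
  if (is.null(lu)) {
    stop(sprintf("missing meta.lastUpdated in %s/%s at %s", rt, id, where),
         call. = FALSE)
  }
  deleted <- FALSE
  for (tag in res[["meta"]][["tag"]]) {
    if (identical(tag[["code"]], "DELETED")) deleted <- TRUE
  }
  payload <- res
  payload[["meta"]] <- NULL  # envelope metadata lives outside the payload
  if (deleted && length(payload) <= 2L) payload <- list()
  fhir_envelope(
    logical_id = id, resource_type = rt, last_updated = lu,
    payload = payload, identifier = first_identifier(payload),
    deleted = deleted
  )
}

first_identifier <- function(res) {
  ids <- res[["identifier"]]
  if (length(ids) == 0L) return("")
  first <- ids[[1]]
  val <- first[["value"]]
  if (is.null(val)) return("")
  sys <- first[["system"]]
  if (is.null(sys)) sys <- ""
  paste0(sys, "|", val)
}

#' Read FHIR resources from a FHIR-gateway table export
#'
#' FHIR-gateway style source dialect: a delimited (CSV) table with header
#' columns `fhir_id`, `type`, `data`, `last_updated_at` and `is_deleted`,
#' mirroring a gateway's relational resource store. The `data` cell holds the
#' serialized FHIR resource (may be empty for deleted rows). Several rows may
#' share a `fhir_id` (resource versions); version collapsing happens later.
#'
#' @param path Path to the CSV file.
#' @return List of [fhir_envelope] objects in row order.
#' @export
read_gateway_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  required <- c("fhir_id", "type", "data", "last_updated_at", "is_deleted")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("missing column ", paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    payload <- list()
    identifier <- ""
    if (nzchar(tab$data[i])) {
      payload <- jsonlite::fromJSON(tab$data[i], simplifyVector = FALSE)
      payload[["meta"]] <- NULL
      if (tolower(tab$is_deleted[i]) == "true" && length(payload) <= 2L) {
        payload <- list()
      }
      identifier <- first_identifier(payload)
    }
    out[[i]] <- fhir_envelope(
      logical_id = tab$fhir_id[i], resource_type = tab$type[i],
      last_updated = tab$last_updated_at[i], payload = payload,
      identifier = identifier,
      deleted = tolower(tab$is_deleted[i]) == "true"
    )
  }
  out
}

#' Write an envelope collection as a source fixture
#'
#' Serializes envelopes in either source dialect so that reading the file back
#' with the matching reader ([read_ndjson()] / [read_gateway_table()]) yields
#' an equal collection. In the NDJSON dialect deleted envelopes are emitted as
#' a resource skeleton whose `meta.tag` carries code `"DELETED"`.
#'
#' @param envelopes List of [fhir_envelope] objects.
#' @param dialect `"ndjson"` or `"gateway_table"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(envelopes, dialect = c("ndjson", "gateway_table"),
                          path) {
  dialect <- match.arg(dialect)
  if (dialect == "ndjson") {
    lines <- vapply(envelopes, function(e) {
      jsonlite::toJSON(envelope_to_resource(e), auto_unbox = TRUE,
                       null = "null", digits = NA)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    tab <- data.frame(
      fhir_id = envelope_field(envelopes, "logical_id"),
      type = envelope_field(envelopes, "resource_type"),
      data = vapply(envelopes, function(e) {
        if (length(e$payload) == 0L) return("")
        as.character(jsonlite::toJSON(envelope_to_resource(e, bare = TRUE),
                                      auto_unbox = TRUE, null = "null",
                                      digits = NA))
      }, character(1)),
      last_updated_at = vapply(envelopes,
                               function(e) fmt_utc(e$last_updated),
                               character(1)),
      is_deleted = ifelse(envelope_field(envelopes, "deleted", "logical"),
                          "true", "false"),
      stringsAsFactors = FALSE
    )
    utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

# Rebuild the full FHIR resource for serialization: payload plus the
# envelope-level metadata (id, resourceType, meta.lastUpdated, deletion tag).
envelope_to_resource <- function(e, bare = FALSE) {
  res <- e$payload
  if (length(res) == 0L) res <- list()
  res[["resourceType"]] <- e$resource_type
  res[["id"]] <- e$logical_id
  meta <- res[["meta"]]
  if (is.null(meta)) meta <- list()
  meta[["lastUpdated"]] <- fmt_utc(e$last_updated)
  if (!bare && e$deleted) {
    meta[["tag"]] <- list(list(system = "urn:omopcdc:lifecycle",
                               code = "DELETED"))
  }
  res[["meta"]] <- meta
  res
}
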