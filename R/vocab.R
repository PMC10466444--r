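#' Read a miniature mapping vocabulary
#'
#' The ETL routes coded clinical events to OMOP tables by the *domain* of the
#' code (cross-domain routing: e.g. an ICD-coded Condition whose code lives in
#' the Procedure domain lands in procedure_occurrence). A full standardized
#' vocabulary is out of scope; instead a miniature vocabulary CSV with columns
#' `concept_id, source_code, source_vocabulary, domain` ships with the package
#' and is loaded into `source_to_concept_map` when a target is initialized.
#'
#' @param path CSV path; defaults to the packaged miniature vocabulary.
#' @return A `data.frame` with the four columns above, of class
#'   `mini_vocabulary`.
#' @export
read_vocabulary <- function(path = system.file("extdata",
                                               "mini_vocabulary.csv",
                                               package = "omopcdc")) {
  vocab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(concept_id = "integer",
                                          source_code = "character",
                                          source_vocabulary = "character",
                                          domain = "character"))
  stopifnot(all(c("concept_id", "source_code", "source_vocabulary",
                  "domain") %in% names(vocab)))
  if (anyDuplicated(vocab[, c("source_code", "source_vocabulary")])) {
    stop("source_code must be unique per source_vocabulary", call. = FALSE)
  }
  bad <- setdiff(unique(vocab$domain), names(DOMAIN_TABLE))
  if (length(bad)) stop("unknown domain(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  class(vocab) <- c("mini_vocabulary", "data.frame")
  vocab
}

#' Route a source code to its OMOP target table
#'
#' Pure lookup: returns the standardized table selected by the code's domain
#' (Condition to condition_occurrence, Measurement to measurement, Observation
#' to observation, Procedure to procedure_occurrence, Drug to drug_exposure)
#' together with its concept id. Codes absent from the vocabulary are never
#' dropped: they fall back to `(observation, 0)` as unmapped content.
#'
#' @param source_code Code value, e.g. `"I10"`.
#' @param source_vocabulary Vocabulary the code belongs to, e.g. `"ICD10GM"`.
#' @param vocab A vocabulary from [read_vocabulary()].
#' @return List with `table` (target table name) and `concept_id`.
#' @export
route_by_domain <- function(source_code, source_vocabulary, vocab) {
  i <- which(vocab$source_code == source_code &
               vocab$source_vocabulary == source_vocabulary)
  if (length(i) == 0L) {
    return(list(table = "observation", concept_id = 0L))
  }
  list(table = unname(DOMAIN_TABLE[vocab$domain[i[1]]]),
       concept_id = vocab$concept_id[i[1]])
}

# Fast vectorized variant used by the engine: named lookup environment.
vocab_index <- function(vocab) {
  idx <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(vocab))) {
    assign(paste0(vocab$source_vocabulary[i], "\r", vocab$source_code[i]),
           list(table = unname(DOMAIN_TABLE[vocab$domain[i]]),
                concept_id = vocab$concept_id[i]),
           envir = idx)
  }
  idx
}

route_indexed <- function(idx, source_code, source_vocabulary) {
  hit <- get0(paste0(source_vocabulary, "\r", source_code), envir = idx,
              inherits = FALSE)
  if (is.null(hit)) list(table = "observation", concept_id = 0L) else hit
}
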