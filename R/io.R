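# UTF-8 line-delimited JSON corpus format: one admission note per line,
# fields in fixed order, with a nested "gold" object (quintet + events).

note_to_json <- function(note) {
  gold <- NULL
  if (!is.null(note$gold))
    gold <- list(label = as.list(unclass(note$gold$label)),
                 events = note$gold$events)
  x <- list(note_id = note$note_id, patient_id = note$patient_id,
            admission_year = note$admission_year,
            age_years = note$age_years, gender = note$gender,
            marital_status = note$marital_status,
            profession = note$profession,
            first_diagnosis = note$first_diagnosis,
            text = note$text)
  if (!is.null(gold)) x$gold <- gold
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

note_from_parsed <- function(x) {
  note <- list(note_id = as.character(x$note_id),
               patient_id = as.character(x$patient_id),
               admission_year = as.integer(x$admission_year),
               age_years = as.integer(x$age_years),
               gender = as.character(x$gender),
               marital_status = as.character(x$marital_status),
               profession = as.character(x$profession),
               first_diagnosis = as.character(x$first_diagnosis),
               text = as.character(x$text))
  if (!is.null(x$gold)) {
    ev <- x$gold$events
    if (is.null(ev) || length(ev) == 0L || NROW(ev) == 0L) {
      ev <- empty_events()
    } else {
      ev <- data.frame(disease_code = as.character(ev$disease_code),
                       relation_term = as.character(ev$relation_term),
                       kinship_degree = as.character(ev$kinship_degree),
                       start = as.integer(ev$start),
                       end = as.integer(ev$end), stringsAsFactors = FALSE)
    }
    note$gold <- list(label = as_fh_label(unlist(x$gold$label)), events = ev)
  }
  note
}

#' Write a corpus to line-delimited JSON
#'
#' @param notes list of admission-note records (as produced by
#'   [generate_cohort()] or [read_corpus()]).
#' @param path output file path (UTF-8; one JSON object per line).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(notes, path) {
  lines <- vapply(notes, function(n) as.character(note_to_json(n)), "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, useBytes = FALSE)
  invisible(path)
}

#' Read a line-delimited JSON corpus
#'
#' `read_corpus(write_corpus(notes, path))` is the identity.
#'
#' @param path corpus file path.
#' @return List of admission-note records.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    x <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                  error = function(e)
                    stop("parse error at line ", i, ": ",
                         conditionMessage(e), call. = FALSE))
    if (is.null(x$note_id) || is.null(x$text))
      stop("parse error at line ", i, ": missing note_id/text fields",
           call. = FALSE)
    note_from_parsed(x)
  })
}

#' Write note-level labels/predictions to JSONL
#'
#' One object per note: `note_id`, quintet `label`, optionally five
#' `proba` values and an `events` array with offsets.
#'
#' @param labels list of records, each with `note_id`, `label`
#'   (quintet), optional `proba`, optional `events`.
#' @param path output path.
#' @param meta optional named list written as a leading `_meta` line
#'   (producing stage, config hash).
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, meta = NULL) {
  lines <- vapply(labels, function(l) {
    x <- list(note_id = l$note_id, label = as.list(unclass(l$label)))
    if (!is.null(l$proba)) x$proba <- as.list(unclass(l$proba))
    if (!is.null(l$events)) x$events <- l$events
    as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  }, "")
  if (!is.null(meta))
    lines <- c(as.character(jsonlite::toJSON(list(`_meta` = meta),
                                             auto_unbox = TRUE)), lines)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con)
  invisible(path)
}

#' Read a JSONL label file
#'
#' @param path label file path.
#' @return List of label records (a `_meta` line, if present, is attached
#'   as the `"meta"` attribute).
#' @export
read_labels <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  meta <- NULL
  if (length(lines) && grepl("^\\{\"_meta\"", lines[1])) {
    meta <- jsonlite::fromJSON(lines[1])$`_meta`
    lines <- lines[-1]
  }
  out <- lapply(seq_along(lines), function(i) {
    x <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                  error = function(e)
                    stop("parse error at line ", i, ": ",
                         conditionMessage(e), call. = FALSE))
    l <- list(note_id = as.character(x$note_id),
              label = as_fh_label(unlist(x$label)))
    if (!is.null(x$proba)) l$proba <- stats::setNames(unlist(x$proba), FH_CODES)
    if (!is.null(x$events)) l$events <- x$events
    l
  })
  attr(out, "meta") <- meta
  out
}
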