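#' Merge note-level quintet labels into one patient-level label
#'
#' Componentwise (bitwise) OR across all of a patient's notes: a category
#' is positive for the patient iff any admission note is positive for it.
#' Commutative, associative and idempotent; equal to the componentwise
#' maximum.
#'
#' @param labels list of quintet labels (or a matrix with 5 columns, one
#'   row per note).
#' @return `fh_label` quintet.
#' @examples
#' merge_labels(list(fh_label(F20 = 1), fh_label(F20 = 1), fh_label(F32 = 1)))
#' @export
merge_labels <- function(labels) {
  if (is.matrix(labels)) labels <- asplit(labels, 1L)
  if (length(labels) == 0L)
    stop("merge_labels() needs at least one label")
  m <- do.call(rbind, lapply(labels, function(l) unclass(as_fh_label(l))))
  as_fh_label(as.integer(apply(m, 2L, max)))
}

#' Collapse kinship degrees into the analysis grouping
#'
#' Second- and third-degree mentions are too rare to analyse separately,
#' so any known degree (first/second/third) collapses to `"any_degree"`;
#' an empty sequence or only-`"unknown"` degrees give `"not_mentioned"`.
#'
#' @param degrees character vector of degrees.
#' @return `"any_degree"` or `"not_mentioned"`.
#' @export
merge_kinship <- function(degrees) {
  if (any(degrees %in% c("first", "second", "third"))) "any_degree"
  else "not_mentioned"
}

#' Build the patient-level analysis table
#'
#' Groups notes by patient, merges note labels with [merge_labels()] and
#' kinship degrees with [merge_kinship()], and derives the diagnosis
#' group (F32/F33 -> MDD, F31 -> BD) and demographics from the earliest
#' admission.  When admissions disagree on the first-diagnosis code the
#' earliest admission wins by default; `strict = TRUE` raises an error
#' instead.
#'
#' @param notes list of admission-note records.
#' @param note_labels list of label records (`note_id`, `label`,
#'   optional `events` carrying `kinship_degree`), e.g. from
#'   [annotate_corpus()] or classifier predictions.
#' @param strict error on patients whose admissions carry conflicting
#'   first-diagnosis codes.
#' @return data.frame, one row per patient: `patient_id`, demographics at
#'   first admission, `diagnosis_group`, the five `fh_*` indicators,
#'   `any_family_history`, `kinship_group`.
#' @export
build_patient_table <- function(notes, note_labels, strict = FALSE) {
  note_ids <- vapply(notes, `[[`, "", "note_id")
  lbl_ids <- vapply(note_labels, `[[`, "", "note_id")
  unknown <- setdiff(lbl_ids, note_ids)
  if (length(unknown))
    stop("labels refer to unknown note id(s): ",
         paste(unknown, collapse = ", "))
  idx <- match(lbl_ids, note_ids)
  scored <- notes[idx]

  pid <- vapply(scored, `[[`, "", "patient_id")
  year <- vapply(scored, function(n)
    as.integer(n$admission_year %||% NA_integer_), NA_integer_)
  rows <- lapply(split(seq_along(scored), pid), function(ii) {
    ii <- ii[order(year[ii], ii)]
    first <- scored[[ii[1L]]]
    codes <- unique(vapply(scored[ii], `[[`, "", "first_diagnosis"))
    if (strict && length(codes) > 1L)
      stop("patient ", first$patient_id,
           " has conflicting first-diagnosis codes: ",
           paste(codes, collapse = ", "))
    lab <- merge_labels(lapply(note_labels[ii], `[[`, "label"))
    degrees <- unlist(lapply(note_labels[ii], function(l) {
      if (is.null(l$events) || NROW(l$events) == 0L) character()
      else l$events$kinship_degree
    }))
    data.frame(patient_id = first$patient_id,
               age_years = first$age_years,
               gender = first$gender,
               marital_status = first$marital_status,
               profession = first$profession,
               first_diagnosis = first$first_diagnosis,
               diagnosis_group = if (first$first_diagnosis == "F31") "BD"
                                 else "MDD",
               t(as.matrix(stats::setNames(as.integer(lab),
                                           paste0("fh_", FH_CODES)))),
               any_family_history = as.integer(any(lab == 1L)),
               kinship_group = merge_kinship(degrees %||% character()),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$patient_id), , drop = FALSE]
  row.names(out) <- NULL
  out
}
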