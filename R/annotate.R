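# sentence terminators and clause separators shared by the scope and
# negation rules (CJK and ASCII punctuation)
SENTENCE_END_CHARS <- c("。", "！", "？", ".", "!", "?", "\n")
CLAUSE_END_CHARS <- c(SENTENCE_END_CHARS,
                      "，", "、", "；", ",", ";")

#' Locate the family-history span of a note
#'
#' Admission notes are single paragraphs mixing family history with
#' present illness, past history and examination findings; the
#' family-history content is cued by a section marker phrase (Chinese
#' 家族史 in the default lexicon).  The span runs from the
#' first section cue to the end of the sentence containing it (the
#' character after its terminator), or to the end of the text when no
#' terminator follows.
#'
#' @param text the note text.
#' @param lexicon an `fh_lexicon`.
#' @return Integer `c(start, end)` (0-based, half-open) or `NULL` when no
#'   cue is present.
#' @export
locate_family_history <- function(text, lexicon) {
  pos <- -1L
  for (cue in unlist(lexicon$section_cues)) {
    p <- regexpr(cue, text, fixed = TRUE)
    if (p > 0 && (pos < 0 || p < pos)) pos <- as.integer(p)
  }
  if (pos < 0) return(NULL)
  chars <- strsplit(substr(text, pos, nchar(text)), "")[[1]]
  term <- which(chars %in% SENTENCE_END_CHARS)
  end <- if (length(term)) pos - 1L + term[1L] else nchar(text)
  c(start = pos - 1L, end = end)
}

#' Extract family-history events from a note
#'
#' Segments the scoped text and pairs every disease term with the nearest
#' preceding kinship term in the same sentence (relation `"unknown"` when
#' there is none).  A disease term whose clause (comma/period-delimited)
#' contains a negation cue is skipped.  Scope `"section"` (the default)
#' restricts matching to the located family-history span, falling back to
#' the full text when no section cue is present; scope `"full"` always
#' scans the whole note.
#'
#' @param text the note text.
#' @param lexicon an `fh_lexicon`.
#' @param scope `"section"` or `"full"`.
#' @param tokenizer_id passed to [segment()].
#' @return data.frame of events (`disease_code`, `relation_term`,
#'   `kinship_degree`, `start`, `end`), sorted by span start; offsets are
#'   0-based half-open into the full note text.
#' @export
extract_events <- function(text, lexicon, scope = c("section", "full"),
                           tokenizer_id = "longest_match") {
  scope <- match.arg(scope)
  offset <- 0L
  scoped <- text
  if (scope == "section") {
    span <- locate_family_history(text, lexicon)
    if (!is.null(span)) {
      scoped <- substr(text, span[1L] + 1L, span[2L])
      offset <- span[1L]
    }
  }
  toks <- segment(scoped, lexicon, tokenizer_id)
  if (!nrow(toks)) return(empty_events())

  dis_map <- unlist(lexicon$disease_terms)
  kin_names <- names(lexicon$kinship_terms)
  neg_cues <- unlist(lexicon$negation_cues)

  is_dis <- toks$token %in% names(dis_map)
  is_kin <- toks$token %in% kin_names
  is_neg <- toks$token %in% neg_cues
  # sentence / clause ids advance after each terminator token
  sent_id <- cumsum(c(0L, utils::head(toks$token %in% SENTENCE_END_CHARS, -1L)))
  clause_id <- cumsum(c(0L, utils::head(toks$token %in% CLAUSE_END_CHARS, -1L)))
  neg_clauses <- unique(clause_id[is_neg])

  hits <- which(is_dis & !(clause_id %in% neg_clauses))
  if (!length(hits)) return(empty_events())

  out <- lapply(hits, function(i) {
    prev_kin <- which(is_kin & seq_len(nrow(toks)) < i &
                        sent_id == sent_id[i])
    rel <- if (length(prev_kin)) toks$token[max(prev_kin)] else NA_character_
    data.frame(disease_code = unname(dis_map[[toks$token[i]]]),
               relation_term = ifelse(is.na(rel), "unknown", rel),
               kinship_degree = if (is.na(rel)) "unknown"
                                else kinship_degree(rel, lexicon),
               start = offset + toks$start[i],
               end = offset + toks$end[i], stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$start), , drop = FALSE]
  row.names(ev) <- NULL
  ev
}

#' Annotate a corpus with the rule-based labeler
#'
#' Runs [extract_events()] and [events_to_label()] over every note.
#' These preliminary rule labels are emitted as final labels (the manual
#' verification step of the original workflow is a human process outside
#' this package); [write_labels()] produces a review-export file for
#' human checking.
#'
#' @param notes list of admission-note records.
#' @param lexicon an `fh_lexicon`.
#' @param scope `"section"` or `"full"` (see [extract_events()]).
#' @return List of label records (`note_id`, `label`, `events`).
#' @export
annotate_corpus <- function(notes, lexicon, scope = "section") {
  lapply(notes, function(note) {
    ev <- extract_events(note$text, lexicon, scope = scope)
    list(note_id = note$note_id, label = events_to_label(ev), events = ev)
  })
}
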