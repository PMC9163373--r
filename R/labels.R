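#' @keywords internal
"_PACKAGE"

#' Fixed label order of the family-history quintet
#'
#' The five ICD-10 family-history categories, in the fixed order used by
#' every quintet label in the package: schizophrenia (F20), depressive
#' episode (F32), bipolar disorder (F31), other non-organic mental
#' disorders (F28) and unspecified non-organic psychosis (F29).
#'
#' @format Character vector of length 5.
#' @export
FH_CODES <- c("F20", "F32", "F31", "F28", "F29")

#' Recognised kinship degrees
#' @format Character vector of length 4.
#' @export
KINSHIP_DEGREES <- c("first", "second", "third", "unknown")

#' Construct a family-history quintet label
#'
#' A quintet is a named integer vector of 0/1 indicators over
#' [FH_CODES], always in that fixed key order.
#'
#' @param F20,F32,F31,F28,F29 binary indicators (0 or 1).
#' @return Named integer vector of class `fh_label`.
#' @examples
#' fh_label(F32 = 1)
#' @export
fh_label <- function(F20 = 0L, F32 = 0L, F31 = 0L, F28 = 0L, F29 = 0L) {
  x <- c(F20 = F20, F32 = F32, F31 = F31, F28 = F28, F29 = F29)
  as_fh_label(x)
}

#' Coerce a length-5 vector to a quintet label
#'
#' Unnamed vectors are taken to already be in [FH_CODES] order; named
#' vectors are reordered.
#'
#' @param x numeric/integer vector of length 5 with values in \{0, 1\}.
#' @return Named integer vector of class `fh_label`.
#' @export
as_fh_label <- function(x) {
  if (length(x) != 5L)
    stop("a family-history label must have exactly 5 indicators, got ",
         length(x))
  if (!is.null(names(x))) {
    if (!setequal(names(x), FH_CODES))
      stop("label names must be exactly ", paste(FH_CODES, collapse = ", "))
    x <- x[FH_CODES]
  } else {
    names(x) <- FH_CODES
  }
  x <- as.integer(x)
  if (!all(x %in% c(0L, 1L)))
    stop("label indicators must be 0 or 1")
  names(x) <- FH_CODES
  structure(x, class = "fh_label")
}

#' Empty event table
#'
#' Canonical zero-row data frame of family-history events, used wherever
#' a note has no extracted or gold events.
#'
#' @return data.frame with columns `disease_code`, `relation_term`,
#'   `kinship_degree`, `start`, `end` (character offsets, 0-based,
#'   half-open).
#' @export
empty_events <- function() {
  data.frame(disease_code = character(), relation_term = character(),
             kinship_degree = character(), start = integer(),
             end = integer(), stringsAsFactors = FALSE)
}

#' Collapse events to a quintet label
#'
#' The indicator for a category is 1 iff at least one event carries that
#' disease code; duplicated events and event order do not matter.
#'
#' @param events data.frame as returned by [extract_events()] (or
#'   [empty_events()]).
#' @return `fh_label` quintet.
#' @examples
#' ev <- data.frame(disease_code = "F32", relation_term = "sister",
#'                  kinship_degree = "first", start = 0L, end = 1L)
#' events_to_label(ev)
#' @export
events_to_label <- function(events) {
  if (is.null(events) || nrow(events) == 0L)
    return(as_fh_label(rep(0L, 5L)))
  codes <- unique(events$disease_code)
  bad <- setdiff(codes, FH_CODES)
  if (length(bad))
    stop("unknown disease code(s): ", paste(bad, collapse = ", "))
  as_fh_label(as.integer(FH_CODES %in% codes))
}
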