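#' Load a phrase lexicon
#'
#' A lexicon bundles the surface vocabulary shared by the synthetic-note
#' generator and the rule annotator: disease terms mapped to the five
#' ICD-10 categories, kinship terms with canonical relation and degree,
#' negation cues, the family-history section cue(s), and the phrase
#' templates used to render synthetic notes.
#'
#' Two lexicons ship with the package:
#' \describe{
#'   \item{`"zh_default"`}{Chinese admission-note phrasing (the default;
#'     matches the clinical setting the package models).}
#'   \item{`"debug_en"`}{romanized templates with identical structure, for
#'     readable tests and examples.}
#' }
#'
#' @param id bundled lexicon id (`"zh_default"` or `"debug_en"`) or a path
#'   to a UTF-8 JSON lexicon file with the same schema.
#' @return A list of class `fh_lexicon`.
#' @export
read_lexicon <- function(id = "zh_default") {
  path <- if (file.exists(id)) id else
    system.file("extdata", paste0("lexicon_", id, ".json"), package = "famhx")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown lexicon id or missing file: ", id)
  lx <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  validate_lexicon(lx)
}

validate_lexicon <- function(lx) {
  stopifnot(is.list(lx))
  need <- c("id", "disease_terms", "kinship_terms", "negation_cues",
            "section_cues", "templates")
  miss <- setdiff(need, names(lx))
  if (length(miss))
    stop("lexicon is missing field(s): ", paste(miss, collapse = ", "))
  dt <- unlist(lx$disease_terms)
  if (anyDuplicated(names(dt)))
    stop("a disease surface term maps to two codes in lexicon ", lx$id)
  bad <- setdiff(unique(dt), FH_CODES)
  if (length(bad))
    stop("lexicon disease codes outside the quintet: ",
         paste(bad, collapse = ", "))
  for (k in lx$kinship_terms) {
    if (!k$degree %in% setdiff(KINSHIP_DEGREES, "unknown"))
      stop("kinship degree must be first/second/third, got: ", k$degree)
  }
  class(lx) <- "fh_lexicon"
  lx
}

#' Kinship degree of a relation term
#'
#' Looks the surface term up in the lexicon's kinship map. Terms absent
#' from the map get degree `"unknown"` (the conventional consanguinity
#' map ships in the lexicon files: first = parents/children/full
#' siblings, second = grandparents/aunts/uncles/nephews/nieces/
#' half-siblings, third = cousins/great-grandparents).
#'
#' @param term surface string (vectorised).
#' @param lexicon an `fh_lexicon`.
#' @return Character vector of degrees in [KINSHIP_DEGREES].
#' @export
kinship_degree <- function(term, lexicon) {
  vapply(term, function(tm) {
    k <- lexicon$kinship_terms[[tm]]
    if (is.null(k)) "unknown" else k$degree
  }, character(1), USE.NAMES = FALSE)
}

# all dictionary surfaces used by the longest-match segmenter
lexicon_dictionary <- function(lexicon) {
  unique(c(names(lexicon$disease_terms), names(lexicon$kinship_terms),
           unlist(lexicon$negation_cues), unlist(lexicon$section_cues),
           unlist(lexicon$templates$wordlist)))
}

disease_terms_of <- function(lexicon, code) {
  dt <- unlist(lexicon$disease_terms)
  names(dt)[dt == code]
}

kinship_terms_of_degree <- function(lexicon, degree) {
  names(lexicon$kinship_terms)[
    vapply(lexicon$kinship_terms, function(k) k$degree, "") == degree]
}
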