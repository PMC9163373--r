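# Tokenizer registry: a dictionary-based longest-match segmenter is the
# default; an external segmenter (e.g. a binding to a general-purpose
# Chinese word segmenter) can be plugged in under its own id.
.tokenizers <- new.env(parent = emptyenv())

#' Register a tokenizer
#'
#' @param id tokenizer id.
#' @param fun function(text, lexicon) returning a data.frame with columns
#'   `token`, `start`, `end` (0-based, half-open character offsets).
#' @export
register_tokenizer <- function(id, fun) {
  stopifnot(is.character(id), length(id) == 1L, is.function(fun))
  assign(id, fun, envir = .tokenizers)
  invisible(id)
}

#' Segment text into tokens with character offsets
#'
#' The default `"longest_match"` tokenizer walks the text and at each
#' position takes the longest dictionary surface (lexicon disease terms,
#' kinship terms, negation cues, section cues and general wordlist) that
#' matches; otherwise an ASCII alphanumeric run is one token; otherwise a
#' single character is one token.  Whitespace is a separator and yields
#' no token.  Concatenating token surfaces (ignoring separators)
#' reconstructs the input; offsets are 0-based, half-open, sorted and
#' non-overlapping.
#'
#' @param text a single string (may be empty).
#' @param lexicon an `fh_lexicon` supplying the dictionary.
#' @param tokenizer_id registered tokenizer id (default
#'   `"longest_match"`).
#' @return data.frame with columns `token`, `start`, `end`.
#' @export
segment <- function(text, lexicon, tokenizer_id = "longest_match") {
  if (!exists(tokenizer_id, envir = .tokenizers, inherits = FALSE))
    stop("unknown tokenizer_id: ", tokenizer_id)
  get(tokenizer_id, envir = .tokenizers)(text, lexicon)
}

longest_match_tokenize <- function(text, lexicon) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text))
    return(data.frame(token = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  chars <- strsplit(text, "", fixed = FALSE)[[1]]
  n <- length(chars)
  dict <- lexicon_dictionary(lexicon)
  by_first <- split(dict, substr(dict, 1L, 1L))
  by_first <- lapply(by_first, function(v) v[order(-nchar(v))])
  is_ws <- grepl("^\\s$", chars)
  is_ascii_alnum <- grepl("^[A-Za-z0-9]$", chars)

  tokens <- character(n); starts <- integer(n); k <- 0L
  i <- 1L
  while (i <= n) {
    cand <- by_first[[chars[i]]]
    matched <- NA_character_
    if (!is.null(cand)) {
      for (term in cand) {
        w <- nchar(term)
        if (i + w - 1L <= n &&
            paste(chars[i:(i + w - 1L)], collapse = "") == term) {
          matched <- term
          break
        }
      }
    }
    if (!is.na(matched)) {
      k <- k + 1L; tokens[k] <- matched; starts[k] <- i - 1L
      i <- i + nchar(matched)
    } else if (is_ws[i]) {
      i <- i + 1L
    } else if (is_ascii_alnum[i]) {
      j <- i
      while (j < n && is_ascii_alnum[j + 1L]) j <- j + 1L
      k <- k + 1L
      tokens[k] <- paste(chars[i:j], collapse = "")
      starts[k] <- i - 1L
      i <- j + 1L
    } else {
      k <- k + 1L; tokens[k] <- chars[i]; starts[k] <- i - 1L
      i <- i + 1L
    }
  }
  tokens <- tokens[seq_len(k)]; starts <- starts[seq_len(k)]
  data.frame(token = tokens, start = starts,
             end = starts + nchar(tokens), stringsAsFactors = FALSE)
}

register_tokenizer("longest_match", longest_match_tokenize)
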