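#' Split a text into sentences
#'
#' Sentences are delimited by runs of terminal punctuation (`.`, `!`, `?`)
#' or by blank lines; an ellipsis therefore counts as a single split point.
#' Empty segments are discarded. A text with no terminator at all is
#' returned as one sentence, so every non-empty document yields at least
#' one sentence.
#'
#' @param text A single character string.
#' @return Character vector of sentence strings (length >= 1).
#' @export
#' @examples
#' tokenize_sentences("Hi there. Bye!")
tokenize_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) {
    stop("empty document", call. = FALSE)
  }
  parts <- strsplit(text, "[.!?]+|\n[ \t]*\n", perl = TRUE)[[1L]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) {
    # punctuation-only text: treat the whole thing as one sentence
    parts <- trimws(text)
  }
  parts
}

#' Tokenize a text into words
#'
#' Splits on whitespace, strips leading and trailing punctuation from each
#' token, and drops tokens that become empty (punctuation-only tokens).
#' Internal punctuation such as apostrophes is kept.
#'
#' @param text A single character string.
#' @param lowercase Lowercase the tokens? Lexical diversity is computed on
#'   lowercased tokens; the readability counts are case-insensitive anyway.
#' @return Character vector of word tokens (possibly empty).
#' @export
#' @examples
#' tokenize_words("The cat, the hat.")
tokenize_words <- function(text, lowercase = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text)) return(character(0))
  toks <- strsplit(trimws(text), "\\s+", perl = TRUE)[[1L]]
  toks <- strip_token_punct(toks)
  toks <- toks[nzchar(toks)]
  if (lowercase) toks <- tolower(toks)
  toks
}

strip_token_punct <- function(tokens) {
  gsub("^[^[:alnum:]]+|[^[:alnum:]]+$", "", tokens, perl = TRUE)
}

#' Count syllables in words (heuristic)
#'
#' Deterministic rule-based syllabification: each contiguous run of the
#' vowels `a e i o u y` counts one syllable; a terminal silent "e" (word
#' ends in "e" but not in consonant + "le") subtracts one; every group of
#' digits counts one syllable; the result is clamped to at least 1.
#' The rules are intentionally simple so that synthetic vocabularies can
#' be built whose true syllable counts the heuristic recovers exactly.
#'
#' @param words Character vector of non-empty word tokens.
#' @return Integer vector of syllable counts, all >= 1.
#' @export
#' @examples
#' count_syllables(c("happy", "cake", "table"))
count_syllables <- function(words) {
  stopifnot(is.character(words))
  if (length(words) == 0L) return(integer(0))
  if (anyNA(words) || any(!nzchar(words))) {
    stop("count_syllables: empty or missing word", call. = FALSE)
  }
  w <- tolower(words)
  digit_groups <- count_matches(w, "[0-9]+")
  wl <- gsub("[0-9]+", "", w, perl = TRUE)
  runs <- count_matches(wl, "[aeiouy]+")
  silent_e <- grepl("e$", wl, perl = TRUE) & !grepl("[^aeiou]le$", wl, perl = TRUE)
  pmax(1L, runs - as.integer(silent_e) + digit_groups)
}

# number of non-overlapping matches of `pattern` in each element of `x`;
# collapses every match to a sentinel char and counts sentinels, which is
# far faster than gregexpr over long vectors
count_matches <- function(x, pattern) {
  y <- gsub(pattern, "\r", x, perl = TRUE)
  nchar(y) - nchar(gsub("\r", "", y, fixed = TRUE))
}
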