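#' Surface statistics of one text
#'
#' Computes the raw counts that feed all four readability formulas:
#' sentences, words, syllables, polysyllabic words (>= 3 syllables),
#' Gunning-Fog complex words (same >= 3 syllable definition, no
#' proper-noun or suffix exclusions), unique lowercased words, and the
#' Linsear Write point tally over the sampled span (first 100 words, or
#' the whole text when shorter; easy word of <= 2 syllables = 1 point,
#' hard word = 3 points).
#'
#' @param text A single character string with at least one word.
#' @return A list with elements `n_sentences`, `n_words`, `n_syllables`,
#'   `n_polysyllables`, `n_complex`, `n_unique_words`, `linsear_points`,
#'   `linsear_sentences`.
#' @export
#' @examples
#' text_stats("The cat sat.")
text_stats <- function(text) {
  sents <- tokenize_sentences(text)
  words <- tokenize_words(text)
  if (length(words) == 0L) stop("no words in document", call. = FALSE)
  syl <- count_syllables(words)
  n_words <- length(words)
  n_sent <- length(sents)
  poly <- syl >= 3L

  span <- seq_len(min(100L, n_words))
  linsear_points <- sum(ifelse(poly[span], 3L, 1L))
  if (n_words <= 100L) {
    linsear_sentences <- n_sent
  } else {
    # number of sentences needed to cover the first 100 words
    per_sent <- vapply(sents, function(s) length(tokenize_words(s)), integer(1))
    cum <- cumsum(per_sent)
    hit <- which(cum >= 100L)
    linsear_sentences <- if (length(hit)) hit[1L] else n_sent
  }

  list(
    n_sentences = n_sent,
    n_words = n_words,
    n_syllables = sum(syl),
    n_polysyllables = sum(poly),
    n_complex = sum(poly),
    n_unique_words = length(unique(tolower(words))),
    linsear_points = linsear_points,
    linsear_sentences = max(1L, linsear_sentences)
  )
}

#' Flesch-Kincaid grade level
#'
#' `0.39 * words/sentence + 11.8 * syllables/word - 15.59`. Negative
#' grades are legal for very simple texts.
#'
#' @param stats A list or data frame with `n_words`, `n_sentences`,
#'   `n_syllables` (vectorized over data-frame columns).
#' @return Numeric grade level.
#' @export
flesch_kincaid <- function(stats) {
  0.39 * stats$n_words / stats$n_sentences +
    11.8 * stats$n_syllables / stats$n_words - 15.59
}

#' SMOG index
#'
#' `1.0430 * sqrt(polysyllables * 30 / sentences) + 3.1291`.
#'
#' @param stats A list or data frame with `n_polysyllables`, `n_sentences`.
#' @return Numeric grade level.
#' @export
smog_index <- function(stats) {
  1.0430 * sqrt(stats$n_polysyllables * 30 / stats$n_sentences) + 3.1291
}

#' Gunning Fog index
#'
#' `0.4 * (words/sentence + 100 * complex/words)` with complex words
#' defined as >= 3 syllables.
#'
#' @param stats A list or data frame with `n_words`, `n_sentences`,
#'   `n_complex`.
#' @return Numeric grade level.
#' @export
gunning_fog <- function(stats) {
  0.4 * (stats$n_words / stats$n_sentences +
           100 * stats$n_complex / stats$n_words)
}

#' Linsear Write grade
#'
#' With `r = points / sentences` over the sampled span: grade `r/2` when
#' `r > 20`, otherwise `r/2 - 1`.
#'
#' @param stats A list or data frame with `linsear_points`,
#'   `linsear_sentences`.
#' @return Numeric grade level.
#' @export
linsear_write <- function(stats) {
  r <- stats$linsear_points / stats$linsear_sentences
  ifelse(r > 20, r / 2, r / 2 - 1)
}

#' Lexical diversity (type-token ratio)
#'
#' Number of unique tokens divided by total tokens. Pass lowercased
#' tokens for the case-folded definition used throughout the package.
#'
#' @param tokens Non-empty character vector of tokens.
#' @return Fraction in (0, 1].
#' @export
lexical_diversity <- function(tokens) {
  stopifnot(is.character(tokens), length(tokens) >= 1L)
  length(unique(tokens)) / length(tokens)
}

#' Score one post
#'
#' Computes the four readability grades, their arithmetic mean, and
#' lexical diversity for a single text. This is the scalar reference
#' path; [score_corpus()] is the vectorized equivalent for whole corpora
#' and the two are tested against each other.
#'
#' @param text A single character string (a post body).
#' @return One-row tibble with `fk`, `smog`, `fog`, `linsear`, `mean4`,
#'   `lexdiv`, `n_words`.
#' @export
#' @examples
#' score_post("The cat sat on the mat. It was a fine day.")
score_post <- function(text) {
  st <- text_stats(text)
  fk <- flesch_kincaid(st)
  sm <- smog_index(st)
  fg <- gunning_fog(st)
  lw <- linsear_write(st)
  tibble::tibble(
    fk = fk, smog = sm, fog = fg, linsear = lw,
    mean4 = (fk + sm + fg + lw) / 4,
    lexdiv = lexical_diversity(tokenize_words(text, lowercase = TRUE)),
    n_words = st$n_words
  )
}

#' Score every post in a corpus
#'
#' Vectorized scoring of all post bodies: one pass of sentence splitting,
#' tokenization and syllable lookup over the whole corpus (syllables are
#' computed once per unique token). Produces the same numbers as
#' [score_post()] applied row by row.
#'
#' @param posts Tibble of posts (as returned by [read_corpus()] or
#'   [generate_corpus()]) with at least a `body` column. Posts should
#'   already have passed [filter_corpus()]; a post with no countable
#'   words is an error.
#' @return `posts` with columns `fk`, `smog`, `fog`, `linsear`, `mean4`,
#'   `lexdiv`, `n_words` appended.
#' @export
score_corpus <- function(posts) {
  stopifnot(is.data.frame(posts), "body" %in% names(posts))
  texts <- posts$body
  n <- length(texts)
  if (n == 0L) {
    out <- posts
    for (col in c("fk", "smog", "fog", "linsear", "mean4", "lexdiv")) {
      out[[col]] <- numeric(0)
    }
    out$n_words <- integer(0)
    return(tibble::as_tibble(out))
  }

  sent_list <- strsplit(texts, "[.!?]+|\n[ \t]*\n", perl = TRUE)
  seg <- unlist(sent_list, use.names = FALSE)
  seg_idx <- rep.int(seq_len(n), lengths(sent_list))
  n_sent <- pmax(1L, tabulate(seg_idx[nzchar(trimws(seg))], nbins = n))

  tok_list <- strsplit(texts, "\\s+", perl = TRUE)
  raw <- unlist(tok_list, use.names = FALSE)
  post_idx <- rep.int(seq_len(n), lengths(tok_list))
  # clean once per unique raw token, then map back
  u_raw <- unique(raw)
  u_map <- match(raw, u_raw)
  clean_u <- strip_token_punct(u_raw)
  nonempty_u <- nzchar(clean_u)
  keep_tok <- nonempty_u[u_map]
  post_idx <- post_idx[keep_tok]
  u_map <- u_map[keep_tok]

  n_words <- tabulate(post_idx, nbins = n)
  if (any(n_words == 0L)) {
    stop("posts with no countable words: run filter_corpus() first (rows ",
         paste(utils::head(which(n_words == 0L), 5L), collapse = ", "), ")",
         call. = FALSE)
  }

  # per-unique-token syllable counts and lowercase ids, mapped back
  syl_u <- integer(length(clean_u))
  syl_u[nonempty_u] <- count_syllables(clean_u[nonempty_u])
  syl <- syl_u[u_map]
  hard <- syl >= 3L

  n_syll <- as.vector(rowsum(syl, post_idx))
  n_poly <- as.vector(rowsum(as.integer(hard), post_idx))

  low_u <- tolower(clean_u)
  lid_u <- match(low_u, unique(low_u))
  tok_id <- lid_u[u_map]
  key <- (as.numeric(post_idx) - 1) * (max(lid_u) + 1) + tok_id
  n_uniq <- tabulate(post_idx[!duplicated(key)], nbins = n)

  # Linsear span: whole text for posts of <= 100 words (the common case);
  # longer posts fall back to the scalar path for the span sentence count.
  starts <- cumsum(c(0L, n_words[-n]))
  rank_in_post <- seq_along(post_idx) - starts[post_idx]
  in_span <- rank_in_post <= 100L
  lin_pts <- as.vector(rowsum(ifelse(hard[in_span], 3L, 1L), post_idx[in_span]))
  lin_sent <- n_sent
  long <- which(n_words > 100L)
  for (i in long) {
    st_i <- text_stats(texts[i])
    lin_pts[i] <- st_i$linsear_points
    lin_sent[i] <- st_i$linsear_sentences
  }

  st <- list(
    n_sentences = n_sent, n_words = n_words, n_syllables = n_syll,
    n_polysyllables = n_poly, n_complex = n_poly,
    linsear_points = lin_pts, linsear_sentences = lin_sent
  )
  fk <- flesch_kincaid(st)
  sm <- smog_index(st)
  fg <- gunning_fog(st)
  lw <- linsear_write(st)

  out <- posts
  out$fk <- fk
  out$smog <- sm
  out$fog <- fg
  out$linsear <- lw
  out$mean4 <- (fk + sm + fg + lw) / 4
  out$lexdiv <- n_uniq / n_words
  out$n_words <- n_words
  tibble::as_tibble(out)
}
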