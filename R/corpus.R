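#' Read a post corpus from JSON Lines
#'
#' One JSON object per line with keys `id`, `author`, `subreddit`,
#' `created_utc`, `body`, and `kind` (`"submission"` or `"comment"`).
#' Malformed lines and records missing a required field are skipped with
#' a warning; their count is attached as attribute `n_malformed`.
#'
#' @param path Path to a JSONL file (UTF-8).
#' @param communities Optional character vector: keep only posts whose
#'   community label is in this set.
#' @return Tibble with columns `post_id`, `member_id`, `community`,
#'   `timestamp`, `kind`, `body`, in file order.
#' @export
read_corpus <- function(path, communities = NULL) {
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  required <- c("id", "author", "subreddit", "created_utc", "body")
  recs <- vector("list", length(lines))
  bad <- 0L
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]]), error = function(e) NULL)
    if (is.null(obj) || !is.list(obj) || !all(required %in% names(obj))) {
      bad <- bad + 1L
      next
    }
    recs[[i]] <- obj
  }
  if (bad > 0L) {
    warning(bad, " malformed line(s) skipped", call. = FALSE)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  posts <- tibble::tibble(
    post_id   = vapply(recs, function(r) as.character(r$id), character(1)),
    member_id = vapply(recs, function(r) as.character(r$author), character(1)),
    community = vapply(recs, function(r) as.character(r$subreddit), character(1)),
    timestamp = vapply(recs, function(r) as.numeric(r$created_utc), numeric(1)),
    kind      = vapply(recs, function(r) {
      if (is.null(r$kind)) "comment" else as.character(r$kind)
    }, character(1)),
    body      = vapply(recs, function(r) as.character(r$body), character(1))
  )
  if (!is.null(communities)) {
    posts <- posts[posts$community %in% communities, , drop = FALSE]
  }
  attr(posts, "n_malformed") <- bad
  posts
}

#' Write a post corpus as JSON Lines
#'
#' Inverse of [read_corpus()]: writes one object per line with keys
#' `id`, `author`, `subreddit`, `created_utc`, `kind`, `body`.
#'
#' @param posts Tibble of posts.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(posts, path) {
  df <- data.frame(
    id = posts$post_id, author = posts$member_id,
    subreddit = posts$community, created_utc = posts$timestamp,
    kind = posts$kind, body = posts$body,
    stringsAsFactors = FALSE
  )
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  jsonlite::stream_out(df, con, verbose = FALSE)
  invisible(path)
}

#' Remove posts carrying a platform deletion marker
#'
#' A post is dropped when its body, after trimming surrounding
#' whitespace, equals one of the markers exactly. Both `"[deleted]"` and
#' `"[removed]"` are platform deletion markers and are matched by
#' default; a body that merely contains a marker is retained.
#'
#' @param posts Tibble of posts.
#' @param markers Character vector of exact deletion markers.
#' @return List with `posts` (retained rows) and `removed` (count).
#' @export
filter_deleted <- function(posts, markers = c("[deleted]", "[removed]")) {
  hit <- trimws(posts$body) %in% markers
  list(posts = posts[!hit, , drop = FALSE], removed = sum(hit))
}

#' Remove posts with fewer than `min_words` words
#'
#' Word counts use the same tokenizer as the readability metrics
#' (whitespace split, punctuation-only tokens dropped), so "word" means
#' the same thing in filtering and in scoring. Posts with exactly
#' `min_words` words are retained.
#'
#' @param posts Tibble of posts.
#' @param min_words Minimum word count (default 5).
#' @return List with `posts` and `removed`.
#' @export
filter_short <- function(posts, min_words = 5) {
  stopifnot(min_words >= 1)
  wc <- count_words(posts$body)
  hit <- wc < min_words
  list(posts = posts[!hit, , drop = FALSE], removed = sum(hit))
}

# vectorized word count with the metrics tokenizer
count_words <- function(texts) {
  n <- length(texts)
  if (n == 0L) return(integer(0))
  tok_list <- strsplit(trimws(texts), "\\s+", perl = TRUE)
  raw <- unlist(tok_list, use.names = FALSE)
  idx <- rep.int(seq_len(n), lengths(tok_list))
  u <- unique(raw)
  ok <- nzchar(strip_token_punct(u))[match(raw, u)]
  tabulate(idx[ok], nbins = n)
}

#' Keep only posts of regular members
#'
#' A regular member has at least `min_posts` surviving posts within one
#' community; membership is evaluated per community, so a member active
#' in two communities is assessed independently in each.
#'
#' @param posts Tibble of posts that already passed [filter_deleted()]
#'   and [filter_short()].
#' @param min_posts Minimum surviving posts (default 4).
#' @return List with `posts` (posts of regular members) and `members`, a
#'   tibble of the retained `(community, member_id)` pairs.
#' @export
select_regular_members <- function(posts, min_posts = 4) {
  stopifnot(min_posts >= 1)
  counts <- dplyr::count(posts, .data$community, .data$member_id)
  keepers <- counts[counts$n >= min_posts, c("community", "member_id")]
  kept <- dplyr::semi_join(posts, keepers, by = c("community", "member_id"))
  list(posts = kept, members = tibble::as_tibble(keepers))
}

#' Apply the full inclusion filter pipeline
#'
#' Runs [filter_deleted()], [filter_short()], then
#' [select_regular_members()], in that fixed order (a member whose only
#' fourth post is short is therefore excluded), and tallies a filter
#' report.
#'
#' @param posts Tibble of posts.
#' @param min_words Minimum words per post (default 5).
#' @param min_posts Minimum posts per member per community (default 4).
#' @param markers Deletion markers for [filter_deleted()].
#' @return List with `posts` (the analyzable set) and `report`, a list
#'   with `n_input`, `n_deleted_removed`, `n_short_removed`,
#'   `n_members_input`, `n_regular_members`, `n_posts_retained`.
#' @export
filter_corpus <- function(posts, min_words = 5, min_posts = 4,
                          markers = c("[deleted]", "[removed]")) {
  n_input <- nrow(posts)
  n_members_input <- nrow(unique(posts[, c("community", "member_id")]))
  d <- filter_deleted(posts, markers)
  s <- filter_short(d$posts, min_words)
  r <- select_regular_members(s$posts, min_posts)
  report <- list(
    n_input = n_input,
    n_deleted_removed = d$removed,
    n_short_removed = s$removed,
    n_members_input = n_members_input,
    n_regular_members = nrow(r$members),
    n_posts_retained = nrow(r$posts)
  )
  list(posts = r$posts, report = report)
}
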